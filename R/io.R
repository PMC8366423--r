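#' Read a reflectivity dataset from ASCII
#'
#' Accepts the standard 3- or 4-column whitespace- or comma-delimited
#' format (Q, R, dR and optionally dQ); lines starting with `#` are
#' comments. If the header records that the data are raw Poisson counts
#' (written by [write_dataset()]), incident counts are reconstructed from
#' `s_i = R_i / dR_i^2` and `N_i = (R_i / dR_i)^2`; otherwise they are
#' flagged unavailable (`NA`), which is sufficient for fitting but not for
#' Fisher information.
#'
#' @param path File path.
#' @return An `"nr_dataset"`; a `dq` field is attached when a fourth
#'   column is present.
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  header <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "[,[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v) || !(length(v) %in% c(3L, 4L)))
      stop("malformed row at line ",
           which(lines == body[i])[1], " of ", path,
           " (need 3 or 4 numeric columns)")
    v
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stop("inconsistent column counts in ", path)
  m <- do.call(rbind, rows)
  if (any(m[, 3] < 0))
    stop("negative dR in ", path)
  if (is.unsorted(m[, 1])) {
    warning("Q values not ascending in ", path, "; sorting")
    m <- m[order(m[, 1]), , drop = FALSE]
  }
  hv <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*[:=]"), header, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^#\\s*", key, "\\s*[:=]\\s*"),
                                    "", ln[1])))
  }
  has_counts <- any(grepl("counts\\s*[:=]\\s*poisson", header))
  if (has_counts && all(m[, 3] > 0)) {
    counts <- (m[, 2] / m[, 3])^2
    incident <- m[, 2] / m[, 3]^2
  } else {
    counts <- rep(NA_real_, nrow(m))
    incident <- rep(NA_real_, nrow(m))
  }
  ds <- structure(list(q = m[, 1], counts = counts, incident = incident,
                       r = m[, 2], dr = m[, 3],
                       angle = hv("angle"), time = hv("time"),
                       seed = hv("seed")),
                  class = "nr_dataset")
  if (ncols == 4L) ds$dq <- m[, 4]
  ds
}

#' Write a reflectivity dataset to ASCII
#'
#' Emits a self-describing `#` header (angle, time, seed, units, and a
#' `counts: poisson` flag when raw counts are carried) followed by Q, R,
#' dR (and dQ if present) at 15 significant digits, so a write/read round
#' trip preserves the numbers to 12 significant digits.
#'
#' @param dataset An `"nr_dataset"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# neutron reflectivity dataset",
    "# columns: Q (1/A)  R  dR"
      , if (!is.null(dataset$dq)) "# fourth column: dQ (1/A)",
    sprintf("# angle: %s", format(dataset$angle)),
    sprintf("# time: %s", format(dataset$time)),
    sprintf("# seed: %s", format(dataset$seed)),
    if (!anyNA(dataset$counts)) "# counts: poisson"
  ), con)
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  for (i in seq_along(dataset$q)) {
    row <- c(fmt(dataset$q[i]), fmt(dataset$r[i]), fmt(dataset$dr[i]))
    if (!is.null(dataset$dq)) row <- c(row, fmt(dataset$dq[i]))
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(path)
}

#' Read an instrument flux profile
#'
#' Two whitespace-delimited columns (wavelength in Angstrom, flux); `#`
#' comment lines are skipped, and a `# reference_angle: <deg>` header is
#' honoured (default 0.3).
#'
#' @param path File path.
#' @return An [flux_profile()].
#' @export
read_flux_profile <- function(path) {
  lines <- readLines(path)
  header <- grep("^\\s*#", lines, value = TRUE)
  ref <- 0.3
  ln <- grep("^#\\s*reference_angle\\s*[:=]", header, value = TRUE)
  if (length(ln))
    ref <- as.numeric(sub("^#\\s*reference_angle\\s*[:=]\\s*", "", ln[1]))
  body <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(body, function(b)
    as.numeric(strsplit(trimws(b), "[,[:space:]]+")[[1]][1:2])))
  flux_profile(m[, 1], m[, 2], reference_angle = ref)
}

#' Write an instrument flux profile
#'
#' @param flux An [flux_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flux_profile <- function(flux, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# instrument flux profile",
               "# columns: wavelength (A)  flux (n/s per bin)",
               sprintf("# reference_angle: %g", flux$reference_angle)),
             con)
  writeLines(sprintf("%.10g %.10g", flux$wavelengths, flux$flux), con)
  invisible(path)
}

#' Read a layer-model configuration file
#'
#' YAML configuration with SLDs in the conventional 1e-6 inverse square
#' Angstrom units (explicit in the key names) and resolution in percent:
#' \preformatted{
#' fronting_sld_e-6: 0.0
#' structure:
#'   - {thickness: 790.7, sld_e-6: 1.795, roughness: 24.5}
#'   - {thickness: 297.9, sld_e-6: 6.385, roughness: 3.50}
#' backing_sld_e-6: 3.354
#' backing_roughness: 12.9
#' scale: 0.783
#' background: 8e-7
#' resolution_dq_q_percent: 2.5
#' }
#' Internally all SLDs are converted to true inverse square Angstrom.
#'
#' @param path File path.
#' @return An [refl_model()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("fronting_sld_e-6", "backing_sld_e-6")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("model config missing key(s): ", paste(missing, collapse = ", "))
  layers <- lapply(cfg$structure, function(ly)
    layer(ly$thickness, ly[["sld_e-6"]] * 1e-6,
          if (is.null(ly$roughness)) 0 else ly$roughness))
  struct <- refl_structure(
    fronting_sld = cfg[["fronting_sld_e-6"]] * 1e-6,
    layers = layers,
    backing_sld = cfg[["backing_sld_e-6"]] * 1e-6,
    backing_roughness = if (is.null(cfg$backing_roughness)) 0
                        else cfg$backing_roughness
  )
  refl_model(
    struct,
    scale = if (is.null(cfg$scale)) 1 else cfg$scale,
    background = if (is.null(cfg$background)) 0 else cfg$background,
    resolution_dq_q = if (is.null(cfg$resolution_dq_q_percent)) 0
                      else cfg$resolution_dq_q_percent / 100
  )
}

#' Read a bilayer configuration file
#'
#' YAML file whose keys mirror the arguments of [bilayer_params()], with
#' SLD-valued keys carrying an `_e-6` suffix (conventional units).
#'
#' @param path File path.
#' @return A [bilayer_params()] object.
#' @export
read_bilayer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (key in names(cfg)) {
    if (grepl("_e-6$", key)) {
      args[[sub("_e-6$", "", key)]] <- cfg[[key]] * 1e-6
    } else if (key == "headgroup_sl_e-4") {
      args$headgroup_sl <- cfg[[key]] * 1e-4
    } else if (key == "tailgroup_sl_e-4") {
      args$tailgroup_sl <- cfg[[key]] * 1e-4
    } else {
      args[[key]] <- cfg[[key]]
    }
  }
  do.call(bilayer_params, args)
}

#' Random test-sample structure
#'
#' Draws a stratified structure on a silicon substrate with each layer's
#' SLD uniform on `[-1, 10] * 1e-6` inverse square Angstrom, thickness
#' uniform on `[20, 1000]` Angstrom and roughness uniform on `[2, 8]`
#' Angstrom; the substrate (backing) SLD is fixed at `2.047e-6`. Fronting
#' is air. Seed-reproducible; the caller's RNG state is untouched.
#'
#' @param n_layers Number of layers, 1 to 6.
#' @param seed Optional integer seed.
#' @return An [refl_structure()].
#' @export
random_structure <- function(n_layers, seed = NULL) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L || n_layers > 6L)
    stop("n_layers must be between 1 and 6")
  .with_seed(seed, {
    layers <- replicate(n_layers, layer(
      thickness = stats::runif(1, 20, 1000),
      sld = stats::runif(1, -1e-6, 10e-6),
      roughness = stats::runif(1, 2, 8)
    ), simplify = FALSE)
    refl_structure(fronting_sld = 0, layers = layers,
                   backing_sld = 2.047e-6,
                   backing_roughness = stats::runif(1, 2, 8))
  })
}

#' Built-in two-layer benchmark model (Si/Cu on quartz)
#'
#' The fitted nickel-free reference sample used throughout the package's
#' examples: a thick Si layer and a Cu layer on a quartz substrate, with
#' experimental scale 0.783, background 8e-7 and 2.5% dQ/Q resolution.
#'
#' @return An [refl_model()].
#' @examples
#' benchmark_model()
#' @export
benchmark_model <- function() {
  refl_model(
    refl_structure(
      fronting_sld = 0,
      layers = list(
        layer(790.7, 1.795e-6, 24.5),   # Si layer
        layer(297.9, 6.385e-6, 3.50)    # Cu layer
      ),
      backing_sld = 3.354e-6,           # quartz
      backing_roughness = 12.9
    ),
    scale = 0.783, background = 8e-7, resolution_dq_q = 0.025
  )
}

#' Serialise a Fisher analysis to text files
#'
#' Writes a human-readable parameter table (name, value, uncertainty, FI
#' diagonal) and, alongside it, a whitespace-delimited information-matrix
#' file with a `#` header naming the parameters.
#'
#' @param analysis A `"fisher_analysis"`.
#' @param path Report file path; the matrix is written to
#'   `<path>.matrix`.
#' @return `path`, invisibly.
#' @export
write_fisher_report <- function(analysis, path) {
  s <- summary(analysis)
  con <- file(path, "w")
  writeLines("# Fisher information analysis", con)
  writeLines(sprintf("# bins: %d", s$n_bins), con)
  writeLines(sprintf("# condition_number: %g", s$condition_number), con)
  writeLines(sprintf("%-24s %16s %16s %16s", "parameter", "value",
                     "uncertainty", "fisher_info"), con)
  for (i in seq_len(nrow(s$table)))
    writeLines(sprintf("%-24s %16.8g %16.8g %16.8g",
                       rownames(s$table)[i], s$table$value[i],
                       s$table$uncertainty[i], s$table$fisher_info[i]),
               con)
  close(con)
  mcon <- file(paste0(path, ".matrix"), "w")
  writeLines(paste("#", paste(analysis$parameters$names, collapse = " ")),
             mcon)
  utils::write.table(analysis$fisher, mcon, row.names = FALSE,
                     col.names = FALSE)
  close(mcon)
  invisible(path)
}
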