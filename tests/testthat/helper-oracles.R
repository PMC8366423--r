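# Independent oracles, deliberately coded apart from the package's
# characteristic-matrix kernel.

# Parratt recursion, bottom-up amplitude ratios, in pure R with complex
# arithmetic. Same conventions as the package (q >= 0, real SLDs,
# Nevot-Croce damping on each interfacial Fresnel coefficient).
parratt_reflectivity <- function(q, struct) {
  sld <- c(struct$fronting_sld,
           vapply(struct$layers, `[[`, numeric(1), "sld"),
           struct$backing_sld)
  d <- c(0, vapply(struct$layers, `[[`, numeric(1), "thickness"), 0)
  sig <- c(vapply(struct$layers, `[[`, numeric(1), "roughness"),
           struct$backing_roughness)
  nm <- length(sld)
  vapply(q, function(qq) {
    k <- sqrt(as.complex((qq / 2)^2 - 4 * pi * (sld - sld[1])))
    # start at the deepest interface and fold upwards
    R <- 0 + 0i
    for (i in seq(nm - 1, 1)) {
      rf <- (k[i] - k[i + 1]) / (k[i] + k[i + 1]) *
        exp(-2 * k[i] * k[i + 1] * sig[i]^2)
      phase <- if (i + 1 <= nm - 1) exp(2i * k[i + 1] * d[i + 1]) else 1
      R <- (rf + R * phase) / (1 + rf * R * phase)
    }
    min(Mod(R)^2, 1)
  }, numeric(1))
}

# closed-form Fresnel reflectivity of a bare interface with Nevot-Croce
# damping
fresnel_reflectivity <- function(q, fronting_sld, backing_sld,
                                 roughness = 0) {
  k0 <- sqrt(as.complex((q / 2)^2))
  k1 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (backing_sld - fronting_sld)))
  amp <- (k0 - k1) / (k0 + k1) * exp(-2 * k0 * k1 * roughness^2)
  pmin(Mod(amp)^2, 1)
}

# closed-form single-layer interference formula (smooth interfaces)
one_layer_reflectivity <- function(q, fronting_sld, layer_sld, backing_sld,
                                   thickness) {
  k0 <- sqrt(as.complex((q / 2)^2))
  k1 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (layer_sld - fronting_sld)))
  k2 <- sqrt(as.complex((q / 2)^2 - 4 * pi * (backing_sld - fronting_sld)))
  r01 <- (k0 - k1) / (k0 + k1)
  r12 <- (k1 - k2) / (k1 + k2)
  ph <- exp(2i * k1 * thickness)
  amp <- (r01 + r12 * ph) / (1 + r01 * r12 * ph)
  pmin(Mod(amp)^2, 1)
}

# brute-force dense trapezoidal convolution for resolution smearing
dense_smear <- function(q, r_fun, resolution_dq_q, n_nodes = 2001L) {
  z <- seq(-3.5, 3.5, length.out = n_nodes)
  w <- dnorm(z)
  w <- w / sum(w)
  sig <- resolution_dq_q * q / (2 * sqrt(2 * log(2)))
  qs <- outer(sig, z) + q
  qs[qs < 0] <- 0
  rv <- r_fun(as.numeric(qs))
  dim(rv) <- dim(qs)
  as.numeric(rv %*% w)
}
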