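# Build an epicell directly from a coordinate matrix (tests craft shapes
# that the circular constructor cannot).
fixture_cell <- function(nodes, A0 = 1, ref_spacing = NULL,
                         cycle_length = NA_real_) {
  nodes <- as.matrix(nodes)
  colnames(nodes) <- c("x", "z")
  if (is.null(ref_spacing))
    ref_spacing <- polygon_perimeter(nodes) / nrow(nodes)
  structure(list(nodes = nodes, A0 = A0, ref_spacing = ref_spacing,
                 cycle_length = cycle_length, age = 0,
                 dividing = is.finite(cycle_length)),
            class = "epicell")
}

# Random star-convex polygon around a centre (simple by construction).
random_polygon <- function(n = 12, r_range = c(0.3, 0.7),
                           center = c(0, 0)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_range[1], r_range[2])
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Internal energy computed independently of the force code (shoelace +
# perimeter written out directly); the finite-difference oracle for the
# internal-force gradient check.
fixture_energy <- function(P, k_A, k_L, A0) {
  n <- nrow(P)
  s <- 0
  for (j in seq_len(n)) {
    jp <- if (j == n) 1L else j + 1L
    s <- s + P[j, 1] * P[jp, 2] - P[jp, 1] * P[j, 2]
  }
  A <- abs(s) / 2
  L <- 0
  for (j in seq_len(n)) {
    jp <- if (j == n) 1L else j + 1L
    L <- L + sqrt(sum((P[jp, ] - P[j, ])^2))
  }
  0.5 * k_A * (A - A0)^2 + 0.5 * k_L * L^2
}

numerical_gradient_force <- function(P, k_A, k_L, A0, h = 1e-6) {
  G <- matrix(0, nrow(P), 2)
  for (j in seq_len(nrow(P))) {
    for (d in 1:2) {
      Pp <- P; Pm <- P
      Pp[j, d] <- Pp[j, d] + h
      Pm[j, d] <- Pm[j, d] - h
      G[j, d] <- -(fixture_energy(Pp, k_A, k_L, A0) -
                     fixture_energy(Pm, k_A, k_L, A0)) / (2 * h)
    }
  }
  G
}
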