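# shared fixtures, all built in code

tetraMesh <- function() {
  triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
               name = "tetra")
}

# open cylinder along z (side wall only; no caps)
openCylinderMesh <- function(radius = 2, len = 30, nA = 40, nC = 24) {
  z <- seq(0, len, length.out = nA)
  th <- 2 * pi * (seq_len(nC) - 1) / nC
  V <- cbind(radius * cos(rep(th, nA)), radius * sin(rep(th, nA)),
             rep(z, each = nC))
  vid <- function(i, j) (i - 1L) * nC + ((j - 1L) %% nC) + 1L
  i <- rep(seq_len(nA - 1L), each = nC)
  j <- rep(seq_len(nC), times = nA - 1L)
  FF <- rbind(cbind(vid(i, j), vid(i, j + 1L), vid(i + 1L, j)),
              cbind(vid(i, j + 1L), vid(i + 1L, j + 1L), vid(i + 1L, j)))
  triangleMesh(V, FF, name = "cylinder")
}

# corresponded cohort: base + sum_k w_k d_k (+ optional iid noise)
linearCohort <- function(base, modes, weights, noiseSd = 0) {
  n <- nrow(weights)
  lapply(seq_len(n), function(s) {
    x <- as.vector(t(base@vertices)) +
      as.numeric(modes %*% weights[s, ])
    V <- matrix(x, ncol = 3, byrow = TRUE)
    if (noiseSd > 0) V <- V + matrix(rnorm(length(V), sd = noiseSd),
                                     nrow(V), 3)
    triangleMesh(V, base@faces, name = sprintf("s%03d", s),
                 validate = FALSE)
  })
}

relRotationDeg <- function(R1, R2) {
  ct <- (sum(diag(R1 %*% t(R2))) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

randomRotationMat <- function(maxAngleDeg) {
  rotationAxisAngle(rnorm(3), runif(1, 0, maxAngleDeg))
}
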