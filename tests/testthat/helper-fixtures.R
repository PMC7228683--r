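# Shared fixtures, built in code. Coarser meshes than the package defaults
# keep unit tests fast; the acceptance tests use the study-condition sizes.

tetra_mesh <- function(scale = 20) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  ibc_mesh(v, f, provenance = "synthetic")
}

# small, fast torso (coarser grid, same geometry family as the defaults)
quick_params <- function(grade = 0, seed = 1, noise = 0.3, edge = 3, ...) {
  torso_params(ptosis_grade = grade, seed = seed, noise = noise, edge = edge,
               ...)
}

quick_case <- function(grade = 0, seed = 1, ...) {
  generate_torso(quick_params(grade = grade, seed = seed, ...))
}

detect_quiet <- function(mesh, ...) suppressMessages(detect_ibc(mesh, ...))

# brute-force nearest-point distances (independent O(n*m) oracle)
brute_nn_dist <- function(P, G) {
  P <- as.matrix(P); G <- as.matrix(G)
  apply(P, 1L, function(q) sqrt(min((G[, 1L] - q[1L])^2 +
                                      (G[, 2L] - q[2L])^2 +
                                      (G[, 3L] - q[3L])^2)))
}

brute_average_distance <- function(A, B) {
  dA <- brute_nn_dist(A, B)
  dB <- brute_nn_dist(B, A)
  (sum(dA) + sum(dB)) / (nrow(as.matrix(A)) + nrow(as.matrix(B)))
}
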