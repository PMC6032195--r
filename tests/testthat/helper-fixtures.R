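## Fixture builders shared across the suite. Everything is generated in
## code; no binary data.

## A bare structure from an N x 3 coordinate matrix.
toy_structure <- function(xyz, chain = "A", name = "CA", resname = "ALA",
                          resid = seq_len(nrow(xyz)), type = "ATOM",
                          element = "C", label = "toy") {
  n <- nrow(xyz)
  groove_structure(data.frame(
    type = rep(type, length.out = n), name = rep(name, length.out = n),
    resname = rep(resname, length.out = n),
    chain = rep(chain, length.out = n), resid = resid,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep(element, length.out = n), b = 0,
    stringsAsFactors = FALSE), label = label)
}

## Two straight parallel C-alpha rows (chains A and B) separated by `sep`
## along -y, with matched spacing so every nearest-neighbour distance
## equals `sep` exactly.
row_groove <- function(n = 10, sep = 13, spacing = 1.5) {
  A <- cbind(spacing * (0:(n - 1)), 0, 0)
  B <- cbind(spacing * (0:(n - 1)), -sep, 0)
  s <- toy_structure(rbind(A, B),
                     chain = rep(c("A", "B"), each = n),
                     resid = c(1:n, 1:n))
  g <- groove_definition("A", "B", c(1, n), c(1, n))
  list(s = s, g = g, A = A, B = B)
}

## Uniform random proper rotation (QR of a Gaussian matrix).
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Apply a rigid motion (rotation then translation) to a structure.
rigid_move <- function(s, rot = diag(3), shift = c(0, 0, 0),
                       chains = NULL) {
  xyz <- atom_xyz(s)
  rows <- if (is.null(chains)) seq_len(nrow(xyz))
          else which(s$atom$chain %in% chains)
  xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE] %*% rot, 2, shift, "+")
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s
}

## Replace all coordinates of a structure (test-side helper).
set_xyz_test <- function(s, xyz) {
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s
}

## Naive double-loop alpha->beta mean-of-minima distance (oracle).
naive_ihd <- function(A, B) {
  mean(vapply(seq_len(nrow(A)), function(i) {
    min(vapply(seq_len(nrow(B)), function(j)
      sqrt(sum((A[i, ] - B[j, ])^2)), numeric(1)))
  }, numeric(1)))
}

## Naive all-pairs count of inter-set distances below a cutoff (oracle).
naive_pair_count <- function(A, B, cutoff) {
  cnt <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    if (sqrt(sum((A[i, ] - B[j, ])^2)) < cutoff) cnt <- cnt + 1L
  cnt
}

## A small trajectory object from a list of N x 3 frames.
frames_trajectory <- function(frames, topo, dt = 0.004) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  groove_trajectory(topo, xyz, dt = dt)
}

## Write PDB text lines for simple CA fixtures with fixed columns.
pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          type = "ATOM", b = 0, element = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, substr(paste0(" ", name), 1, 4), "", resname,
          chain, resid, x, y, z, 1, b, element)
}
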