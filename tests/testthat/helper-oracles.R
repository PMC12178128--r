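# Independent oracles and fixture builders used across the test files.
# Each oracle takes a route disjoint from the implementation it checks.

# --- Horn quaternion superposition: closed-form optimal RMSD via the
# largest eigenvalue of the 4x4 quaternion matrix. Independent of the
# SVD-based Kabsch route.
quaternion_rmsd <- function(mobile, ref) {
  n <- nrow(mobile)
  p <- scale(mobile, scale = FALSE)
  q <- scale(ref, scale = FALSE)
  m <- crossprod(p, q)  # Sxy etc.
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  gp <- sum(p^2) + sum(q^2)
  sqrt(max(0, (gp - 2 * lambda)) / n)
}

# --- Dense rotation-grid + translation brute force for the TM-score, with
# Nelder-Mead polish of the best grid starts. The objective is evaluated
# directly from the definition; no subset-seeded refinement is involved.
euler_rotation <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
  rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

tm_grid_oracle <- function(model, reference, normalize_length = NULL,
                           n_polish = 30L) {
  mob <- model$coords[, "CA", ]
  ref <- reference$coords[, "CA", ]
  l_norm <- if (is.null(normalize_length)) length(reference) else normalize_length
  d0 <- if (l_norm <= 15) 0.5 else max(0.5, 1.24 * (l_norm - 15)^(1 / 3) - 1.8)
  cm <- colMeans(mob); cr <- colMeans(ref)
  mob0 <- sweep(mob, 2, cm)
  ref0 <- sweep(ref, 2, cr)
  score_of <- function(par) {
    r <- euler_rotation(par[1], par[2], par[3])
    moved <- mob0 %*% t(r) + matrix(par[4:6], nrow(mob0), 3, byrow = TRUE)
    d2 <- rowSums((moved - ref0)^2)
    sum(1 / (1 + d2 / d0^2))
  }
  grid_a <- seq(0, 2 * pi, length.out = 19)[-19]
  grid_b <- seq(0, pi, length.out = 10)
  grid_c <- seq(0, 2 * pi, length.out = 19)[-19]
  starts <- expand.grid(a = grid_a, b = grid_b, c = grid_c)
  vals <- apply(starts, 1, function(p) score_of(c(p, 0, 0, 0)))
  top <- order(-vals)[seq_len(n_polish)]
  best <- max(vals)
  jitters <- rbind(c(0, 0, 0, 0, 0, 0),
                   c(0.2, -0.15, 0.1, 0.8, -0.6, 0.4),
                   c(-0.25, 0.2, -0.3, -0.5, 0.9, -0.7))
  for (i in top) {
    for (k in seq_len(nrow(jitters))) {
      o <- stats::optim(c(as.numeric(starts[i, ]), 0, 0, 0) + jitters[k, ],
                        function(p) -score_of(p), method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-11))
      if (-o$value > best) best <- -o$value
    }
  }
  best / l_norm
}

# --- Brute-force pair-enumeration lDDT (loops, no vectorized matrices).
lddt_bruteforce <- function(model, reference, radius = 15,
                            thresholds = c(0.5, 1, 2, 4)) {
  n <- length(reference)
  ca_m <- model$coords[, "CA", ]
  ca_r <- reference$coords[, "CA", ]
  per_sum <- rep(0, n); per_n <- rep(0L, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < 2) next
      dr <- sqrt(sum((ca_r[i, ] - ca_r[j, ])^2))
      if (dr > radius) next
      dm <- sqrt(sum((ca_m[i, ] - ca_m[j, ])^2))
      f <- mean(abs(dm - dr) < thresholds)
      per_sum[i] <- per_sum[i] + f; per_n[i] <- per_n[i] + 1L
      per_sum[j] <- per_sum[j] + f; per_n[j] <- per_n[j] + 1L
    }
  }
  keep <- per_n > 0
  list(global = mean(per_sum[keep] / per_n[keep]),
       per_residue = ifelse(keep, per_sum / pmax(per_n, 1L), NA))
}

# --- Rank-then-Pearson Spearman oracle.
spearman_bruteforce <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- Fixture builders -------------------------------------------------

random_rigid <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1]),
    2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1]),
    2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  list(rotation = r, translation = rnorm(3, 0, 10))
}

transform_structure <- function(structure, rigid) {
  coords <- structure$coords
  for (a in 1:5) {
    m <- coords[, a, ]
    if (is.null(dim(m))) m <- matrix(m, 1, 3)
    coords[, a, ] <- m %*% t(rigid$rotation) +
      matrix(rigid$translation, nrow(m), 3, byrow = TRUE)
  }
  protein_structure(coords, structure$sequence, structure$atom_mask,
                    structure$residue_ids, structure$chain_id)
}

# A hand-written PDB block: three residues, all five atoms present.
pdb_block_3res <- function() {
  st <- make_toy_native(8, "helix", seed = 1)
  # trim to 3 residues for hand-sized fixtures
  coords <- st$coords[1:3, , , drop = FALSE]
  sub <- protein_structure(coords, substr(st$sequence, 1, 3))
  write_pdb(sub)
}

# Structure with a chosen per-residue displacement applied along x.
displaced_structure <- function(reference, shifts) {
  coords <- reference$coords
  for (i in seq_along(shifts)) coords[i, , 1] <- coords[i, , 1] + shifts[i]
  protein_structure(coords, reference$sequence, reference$atom_mask,
                    reference$residue_ids, reference$chain_id)
}
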