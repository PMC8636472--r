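# shared fixtures, built in code at test time

c9_22mer <- function() expand_repeat("GGGGCC", 3, "GGGG", name = "C9-22mer")

mc9_22mer <- function() {
  s <- c9_22mer()
  apply_methylation(s, find_cpg_sites(s))
}

# independent brute-force CpG scan (0-based)
cpg_oracle <- function(str) {
  b <- strsplit(str, "")[[1]]
  out <- integer(0)
  for (i in seq_len(length(b) - 1L))
    if (b[i] == "C" && b[i + 1L] == "G") out <- c(out, i - 1L)
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# grid-search oracle for the constrained decomposition
decompose_grid_oracle <- function(s, basis, step = 1e-4) {
  xs <- seq(0, 1, by = step)
  rss <- vapply(xs, function(x)
    sum((s$ellipticity - x * basis$ap$ellipticity -
           (1 - x) * basis$p$ellipticity)^2), numeric(1))
  xs[which.min(rss)]
}

# a non-GQ control structure: guanines strung out on a line, no Hoogsteen
# contacts possible
linear_g_structure <- function(n = 8) {
  tpl <- quadstruct:::.nt_templates$DG
  pieces <- lapply(seq_len(n), function(i) {
    xyz <- sweep(tpl, 2, c(12 * i, 0, 0), "+")
    data.frame(elety = rownames(tpl), resid = "DG", chain = "A", resno = i,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  gq_structure(do.call(rbind, pieces))
}

# apply a rigid motion (fixed rotation + translation) to a structure
rotate_structure <- function(s, angles = c(0.3, 1.1, -0.7), shift = c(5, -3, 8)) {
  R <- rot_xyz(angles)
  X <- as.matrix(s$atom[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, shift, "+")
  s$atom$x <- X[, 1]; s$atom$y <- X[, 2]; s$atom$z <- X[, 3]
  s
}

rot_xyz <- function(a) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# static trajectory: n identical copies of the model's coordinates
static_trajectory <- function(s, n_frames = 5) {
  X <- as.matrix(s$atom[, c("x", "y", "z")])
  gq_trajectory(s, array(rep(X, n_frames), c(nrow(X), 3, n_frames)))
}
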