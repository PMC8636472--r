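#' Construct a trajectory over a fixed atom roster
#'
#' Frames share the topology's atom roster; coordinates are held as an
#' `n_atoms x 3 x n_frames` array.
#'
#' @param topology A [gq_structure] providing atom/residue bookkeeping.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (a single frame may
#'   be given as an `n_atoms x 3` matrix).
#' @param frame_interval_ps Time between recorded frames in ps.
#' @return An object of class `gq_trajectory`.
#' @export
gq_trajectory <- function(topology, coords, frame_interval_ps = 100) {
  stopifnot(inherits(topology, "gq_structure"))
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(topology$atom))
  if (!all(is.finite(coords))) stop("non-finite trajectory coordinates")
  structure(list(topology = topology, coords = coords,
                 frame_interval_ps = frame_interval_ps),
            class = "gq_trajectory")
}

#' @export
print.gq_trajectory <- function(x, ...) {
  cat(sprintf("<gq_trajectory> %d frames x %d atoms, every %g ps\n",
              dim(x$coords)[3], dim(x$coords)[1], x$frame_interval_ps))
  invisible(x)
}

#' @export
length.gq_trajectory <- function(x) dim(x$coords)[3]

.frame <- function(traj, i) traj$coords[, , i]

#' Optimal rigid-body (Kabsch) superposition
#'
#' Least-squares rotation + translation of `mobile` onto `reference` over a
#' selection of atoms, via SVD of the covariance matrix with the proper
#' rotation enforced (determinant +1).  The whole mobile frame is
#' transformed; the RMSD is over the selection.
#'
#' @param mobile,reference `n x 3` coordinate matrices over the same roster.
#' @param selection Integer/logical row index of the atoms to superpose
#'   (default: all).
#' @return List: `coords` (transformed mobile), `rmsd` (A, over selection),
#'   `rotation`, `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            all(dim(mobile) == dim(reference)), ncol(mobile) == 3L)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  M <- mobile[selection, , drop = FALSE]
  R0 <- reference[selection, , drop = FALSE]
  if (nrow(M) < 3L)
    stop("degenerate selection: need at least 3 atoms to superpose")
  cm <- colMeans(M); cr <- colMeans(R0)
  A <- sweep(M, 2, cm); B <- sweep(R0, 2, cr)
  if (svd(A)$d[2] < 1e-8)
    stop("degenerate selection: selected atoms are (nearly) collinear")
  sv <- svd(t(A) %*% B)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(mobile, 2, cm) %*% t(Rm)
  out <- sweep(out, 2, cr, "+")
  fitted_sel <- out[selection, , drop = FALSE]
  list(coords = out,
       rmsd = sqrt(mean(rowSums((fitted_sel - R0)^2))),
       rotation = Rm, translation = cr - as.vector(Rm %*% cm))
}

# heavy-atom row indices of the tetrad guanines; falls back (with a
# warning) to all heavy atoms when no tetrads are detectable
.tetrad_selection <- function(traj, tetrads = NULL) {
  at <- traj$topology$atom
  heavy <- at$elesy != "H"
  if (is.null(tetrads)) tetrads <- detect_tetrads(traj$topology)
  if (!length(tetrads)) {
    warning("no tetrads found: superposing on all heavy atoms")
    return(which(heavy))
  }
  keys <- unlist(lapply(tetrads, function(tt)
    paste(tt$residues$chain, tt$residues$resno)))
  which(heavy & paste(at$chain, at$resno) %in% keys)
}

#' Per-residue RMSD over a trajectory
#'
#' Each frame is globally superposed on the reference over the tetrad
#' guanine heavy atoms (the rigid core), then the RMSD of each residue's
#' heavy atoms is computed per frame; the mean over frames is reported per
#' residue.
#'
#' @param traj A [gq_trajectory].
#' @param reference Reference frame coordinates (default: frame 1).
#' @param tetrads Optional pre-computed tetrads of the topology.
#' @return List: `per_residue` (`data.frame` with `chain`, `resno`, `resid`,
#'   `mean_rmsd_A`), `series` (`n_frames x n_residues` matrix),
#'   `selection` (atom rows used for superposition).
#' @export
per_residue_rmsd <- function(traj, reference = NULL, tetrads = NULL) {
  stopifnot(inherits(traj, "gq_trajectory"))
  if (is.null(reference)) reference <- .frame(traj, 1L)
  at <- traj$topology$atom
  sel <- .tetrad_selection(traj, tetrads)
  res <- .residue_table(traj$topology)
  rows <- lapply(seq_len(nrow(res)), function(i)
    which(at$chain == res$chain[i] & at$resno == res$resno[i] & at$elesy != "H"))
  nf <- length(traj)
  series <- matrix(NA_real_, nf, nrow(res))
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(.frame(traj, f), reference, sel)$coords
    d2 <- rowSums((fit - reference)^2)
    series[f, ] <- vapply(rows, function(r) sqrt(mean(d2[r])), numeric(1))
  }
  list(per_residue = data.frame(res, mean_rmsd_A = colMeans(series)),
       series = series, selection = sel)
}

#' Per-residue RMSF over a trajectory
#'
#' Frames are superposed (over the tetrad-guanine heavy atoms) onto their
#' time-averaged structure, the average is recomputed once, and the atomic
#' fluctuation `RMSF = sqrt(mean_t |r(t) - rbar|^2)` is averaged over each
#' residue's heavy atoms (unweighted).
#'
#' @param traj A [gq_trajectory] with >= 2 frames.
#' @param tetrads Optional pre-computed tetrads of the topology.
#' @return `data.frame` with `chain`, `resno`, `resid`, `rmsf_A`.
#' @export
per_residue_rmsf <- function(traj, tetrads = NULL) {
  stopifnot(inherits(traj, "gq_trajectory"))
  nf <- length(traj)
  if (nf < 2L)
    stop("RMSF is undefined for a single frame")
  at <- traj$topology$atom
  sel <- .tetrad_selection(traj, tetrads)
  fitted <- traj$coords
  ref <- .frame(traj, 1L)
  for (iter in 1:2) {                    # fit to mean, re-mean, re-fit once
    for (f in seq_len(nf))
      fitted[, , f] <- kabsch_superpose(fitted[, , f], ref, sel)$coords
    ref <- apply(fitted, c(1, 2), mean)
  }
  dev2 <- sweep(fitted, c(1, 2), ref)^2
  atom_rmsf <- sqrt(apply(dev2, 1, sum) / nf)
  res <- .residue_table(traj$topology)
  rmsf <- vapply(seq_len(nrow(res)), function(i) {
    r <- which(at$chain == res$chain[i] & at$resno == res$resno[i] &
                 at$elesy != "H")
    mean(atom_rmsf[r])
  }, numeric(1))
  data.frame(res, rmsf_A = rmsf)
}

# angle (deg, folded into [0, 90]) between two unit plane normals
.plane_angle <- function(n1, n2) {
  cs <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(min(1, cs)) * 180 / pi
}

#' Per-tetrad buckle displacement over a trajectory
#'
#' For every frame and tetrad, the tetrad mean plane is fitted by total
#' least squares over the four guanines' purine ring atoms, each base's own
#' ring plane is fitted the same way, and the base buckle is the angle
#' between base normal and tetrad normal folded into `[0, 90]` degrees.  The
#' tetrad's buckle displacement is the mean of its four base angles
#' (`signed = TRUE` instead signs each base angle by the projection of its
#' normal displacement onto the stack axis).  The summary reports mean and
#' quartiles (linear-interpolation convention) per tetrad.
#'
#' @param traj A [gq_trajectory].
#' @param tetrads Tetrads of the topology (default: detected from it).
#' @param signed Use signed base angles instead of unsigned.
#' @return List: `series` (`n_frames x n_tetrads` matrix, degrees),
#'   `summary` (`data.frame` with `tetrad`, `mean`, `q1`, `median`, `q3`).
#' @export
tetrad_buckle_series <- function(traj, tetrads = NULL, signed = FALSE) {
  stopifnot(inherits(traj, "gq_trajectory"))
  if (is.null(tetrads)) tetrads <- detect_tetrads(traj$topology)
  if (!length(tetrads)) stop("no tetrads to analyse")
  at <- traj$topology$atom
  ring_rows <- lapply(tetrads, function(tt)
    lapply(seq_len(4L), function(k)
      which(at$chain == tt$residues$chain[k] & at$resno == tt$residues$resno[k] &
              at$elety %in% .purine_ring_atoms)))
  nf <- length(traj)
  nt <- length(tetrads)
  series <- matrix(NA_real_, nf, nt)
  axis <- if (nt >= 2L) {
    C <- do.call(rbind, lapply(tetrads, `[[`, "centroid"))
    svd(sweep(C, 2, colMeans(C)))$v[, 1]
  } else tetrads[[1]]$normal
  for (f in seq_len(nf)) {
    X <- .frame(traj, f)
    for (t in seq_len(nt)) {
      rows <- ring_rows[[t]]
      if (any(lengths(rows) < 3L)) {
        warning("tetrad ", t, " missing ring atoms; buckle set to NA")
        next
      }
      tet_pl <- .fit_plane(X[unlist(rows), , drop = FALSE])
      ang <- vapply(rows, function(r) {
        base_pl <- .fit_plane(X[r, , drop = FALSE])
        a <- .plane_angle(base_pl$normal, tet_pl$normal)
        if (signed) {
          sgn <- sign(sum((base_pl$centroid - tet_pl$centroid) * axis))
          if (sgn != 0) a <- a * sgn
        }
        a
      }, numeric(1))
      series[f, t] <- mean(ang)
    }
  }
  qs <- t(apply(series, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
                na.rm = TRUE, type = 7))
  list(series = series,
       summary = data.frame(tetrad = seq_len(nt) - 1L,
                            mean = colMeans(series, na.rm = TRUE),
                            q1 = qs[, 1], median = qs[, 2], q3 = qs[, 3]))
}

#' Combined trajectory stability statistics
#'
#' Convenience wrapper computing per-residue RMSD, per-residue RMSF and the
#' per-tetrad buckle series in one call.
#'
#' @param traj A [gq_trajectory].
#' @param tetrads Optional pre-computed tetrads.
#' @return List with elements `rmsd`, `rmsf`, `buckle` as returned by the
#'   individual functions.
#' @export
traj_stats <- function(traj, tetrads = NULL) {
  if (is.null(tetrads)) tetrads <- detect_tetrads(traj$topology)
  list(rmsd = per_residue_rmsd(traj, tetrads = tetrads),
       rmsf = per_residue_rmsf(traj, tetrads = tetrads),
       buckle = tetrad_buckle_series(traj, tetrads = tetrads))
}

#' Read / write a trajectory as multi-model PDB
#'
#' Binary MD formats are out of scope; trajectories are interchanged as
#' multi-model PDB (`MODEL`/`ENDMDL` blocks with a consistent atom roster).
#'
#' @param path PDB file path.
#' @param frame_interval_ps Frame spacing metadata for the returned object.
#' @param traj A [gq_trajectory] (for writing).
#' @return `read_multimodel_pdb` returns a [gq_trajectory].
#' @export
read_multimodel_pdb <- function(path, frame_interval_ps = 100) {
  # roster consistency pre-check with a model-numbered error
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    counts <- vapply(seq_along(starts), function(i)
      sum(rec[starts[i]:ends[i]] %in% c("ATOM  ", "HETATM")), integer(1))
    if (length(unique(counts)) != 1L)
      stop("format error: model ", which(counts != counts[1])[1],
           " has a different atom roster (", counts[which(counts != counts[1])[1]],
           " vs ", counts[1], " atoms)")
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  at$chain[is.na(at$chain)] <- "A"
  topo <- gq_structure(data.frame(elety = at$elety, resid = at$resid,
                                  chain = at$chain, resno = at$resno,
                                  x = at$x, y = at$y, z = at$z,
                                  elesy = at$elesy, o = at$o, b = at$b,
                                  stringsAsFactors = FALSE))
  nf <- nrow(p$xyz)
  coords <- array(NA_real_, c(nrow(at), 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(p$xyz[f, ], ncol = 3L, byrow = TRUE)
  gq_trajectory(topo, coords, frame_interval_ps)
}

#' @rdname read_multimodel_pdb
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "gq_trajectory"))
  at <- traj$topology$atom
  nf <- length(traj)
  xyz <- t(vapply(seq_len(nf), function(f) as.vector(t(.frame(traj, f))),
                  numeric(3L * nrow(at))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = at$o, b = at$b, elesy = at$elesy)
  invisible(path)
}
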