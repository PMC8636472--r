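# In-plane placement of the corner-0 guanine of the idealized G-tetrad:
# (tx, ty, phi) applied to the canonical base template, solved once so that
# the C4-symmetric copies satisfy Hoogsteen N1...O6 and N2...N7 ~ 2.9 A
# with an O6 channel radius ~ 2.4 A and no inter-base contact < 2.6 A.
.tetrad_placement <- c(tx = -5.066022, ty = 4.568546, phi = 12.139345)

.rot_z <- function(theta)
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta),  cos(theta), 0),
        c(0, 0, 1))

# rigid transform of template coords: in-plane placement, then corner/twist
# rotation about the stack axis, then vertical rise
.place_template <- function(X, corner, layer, rise, twist_rad) {
  p <- .tetrad_placement
  Y <- X %*% t(.rot_z(p[["phi"]]))
  Y[, 1] <- Y[, 1] + p[["tx"]]
  Y[, 2] <- Y[, 2] + p[["ty"]]
  Y <- Y %*% t(.rot_z(corner * pi / 2 + layer * twist_rad))
  Y[, 3] <- Y[, 3] + layer * rise
  Y
}

.atoms_df <- function(names, xyz, resid, chain, resno) {
  data.frame(elety = names, resid = resid, chain = chain, resno = resno,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             elesy = vapply(names, .element_of, character(1)),
             o = 1, b = 0, eleno = 0, stringsAsFactors = FALSE)
}

# maximal runs of G in a base vector: data.frame(start, end, len), 1-based
.g_runs <- function(bases) {
  r <- rle(bases == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             len = r$lengths[r$values])
}

#' Build an idealized intramolecular G-quadruplex model
#'
#' Constructs a deterministic, unrefined atomic model of a unimolecular GQ
#' from a repeat sequence with four guanine tracts of equal length: stacked
#' planar G-tetrads built from an idealized guanine template arranged
#' C4-symmetrically (Hoogsteen N1...O6 and N2...N7 distances ~ 2.9 A, O6
#' channel radius ~ 2.4 A), with consecutive tetrads separated by `rise` and
#' rotated by `twist`.  Loop residues are placed on arcs outside the tetrad
#' stack at `loop_radius`.  Residues are represented by their base heavy
#' atoms plus C1' (a base-level model: sufficient for tetrad detection,
#' buckle/plane analysis, 5mC editing and the synthetic trajectories).
#'
#' The quartet plane arrangement is identical for both topologies -- as in
#' real GQs, where antiparallel strand orientation is absorbed by syn/anti
#' glycosidic torsions rather than a different quartet.  `topology` controls
#' the strand threading: `"parallel"` runs every tract 5'->3' up the stack;
#' `"antiparallel"` alternates tract direction.
#'
#' @param sequence An [oligo_seq] (or string) containing exactly 4 G-tracts
#'   of equal length >= 2, e.g. `(GGGGCC)3GGGG`.
#' @param topology `"antiparallel"` (default) or `"parallel"`.
#' @param rise Inter-tetrad rise in Angstrom (default 3.3).
#' @param twist Inter-tetrad twist in degrees (default 30).
#' @param loop_radius Radius of the loop arcs in Angstrom (default 13).
#' @return A single-chain [gq_structure], one residue per base.
#' @examples
#' gq <- build_ideal_gq(expand_repeat("GGGGCC", 3, "GGGG"), "antiparallel")
#' @export
build_ideal_gq <- function(sequence, topology = c("antiparallel", "parallel"),
                           rise = 3.3, twist = 30, loop_radius = 13) {
  topology <- match.arg(topology)
  if (!inherits(sequence, "oligo_seq")) sequence <- oligo_seq(sequence)
  bases <- sequence$bases
  runs <- .g_runs(bases)
  runs <- runs[runs$len >= 2L, , drop = FALSE]
  if (nrow(runs) != 4L || length(unique(runs$len)) != 1L)
    stop("topology error: sequence must contain exactly 4 G-tracts of ",
         "equal length >= 2")
  L <- runs$len[1]
  twist_rad <- twist * pi / 180

  # tract membership and (corner, layer) for each tract guanine
  corner <- layer <- rep(NA_integer_, length(bases))
  for (t in seq_len(4L)) {
    pos <- runs$start[t]:runs$end[t]
    j <- seq_along(pos) - 1L
    corner[pos] <- t - 1L
    down <- topology == "antiparallel" && (t %% 2L == 0L)
    layer[pos] <- if (down) L - 1L - j else j
  }

  g_tpl_names <- c(.base_atoms$DG, "C1'")
  g_tpl <- .nt_templates$DG[g_tpl_names, , drop = FALSE]

  pieces <- vector("list", length(bases))
  for (i in seq_along(bases)) {
    resid <- paste0("D", bases[i])
    if (!is.na(corner[i])) {
      xyz <- .place_template(g_tpl, corner[i], layer[i], rise, twist_rad)
      pieces[[i]] <- .atoms_df(g_tpl_names, xyz, resid, "A", i)
    } else {
      # loop/overhang residue on an outer arc between the flanking tracts
      prev_t <- which(runs$end < i)
      next_t <- which(runs$start > i)
      t0 <- if (length(prev_t)) max(prev_t) else 1L
      t1 <- if (length(next_t)) min(next_t) else 4L
      a0 <- (t0 - 1L) * 90; a1 <- if (t1 > t0) (t1 - 1L) * 90 else a0 + 90
      z0 <- if (length(prev_t)) layer[runs$end[t0]] * rise else 0
      z1 <- if (length(next_t)) layer[runs$start[t1]] * rise else z0
      span_lo <- if (length(prev_t)) runs$end[t0] else runs$start[t1] - 1L
      span_hi <- if (length(next_t)) runs$start[t1] else runs$end[t0] + 1L
      f <- (i - span_lo) / (span_hi - span_lo)
      theta <- (a0 + f * (a1 - a0)) * pi / 180
      ctr <- c(loop_radius * cos(theta), loop_radius * sin(theta),
               z0 + f * (z1 - z0))
      tn <- c(.base_atoms[[resid]], "C1'")
      xyz <- .nt_templates[[resid]][tn, , drop = FALSE] %*% t(.rot_z(theta))
      xyz <- sweep(xyz, 2, ctr, "+")
      pieces[[i]] <- .atoms_df(tn, xyz, resid, "A", i)
    }
  }
  gq_structure(do.call(rbind, pieces),
               notes = sprintf("idealized %s GQ, %d tetrads (unrefined)",
                               topology, L))
}

#' Build an idealized tetramolecular (four-strand) G-quadruplex fixture
#'
#' Four identical strands, one per tetrad corner, threaded in parallel
#' through the same idealized quartet geometry as [build_ideal_gq()].  Each
#' strand's guanine run forms the tetrad core; non-guanine residues extend
#' the stack axis above/below their strand's run.  Unlike the
#' intramolecular builder this emits full heavy-atom nucleotides (phosphate,
#' sugar, base), so the strand-editing operations ([delete_residues()],
#' [mutate_base()], [append_residue_3prime()], [join_strands()]) can be
#' exercised on it.  Geometry is rigid-template and unrefined.
#'
#' @param strand Strand sequence containing one guanine run, default
#'   `"TTGGGGT"`.
#' @param chains Chain identifiers, default A-D.
#' @param rise,twist As in [build_ideal_gq()].
#' @return A four-chain [gq_structure].
#' @export
build_tetramolecular_gq <- function(strand = "TTGGGGT",
                                    chains = c("A", "B", "C", "D"),
                                    rise = 3.3, twist = 30) {
  sq <- if (inherits(strand, "oligo_seq")) strand else oligo_seq(strand)
  bases <- sq$bases
  runs <- .g_runs(bases)
  runs <- runs[runs$len >= 2L, , drop = FALSE]
  if (nrow(runs) != 1L)
    stop("topology error: strand must contain exactly one guanine run")
  twist_rad <- twist * pi / 180
  layer <- seq_along(bases) - runs$start[1]   # guanine run at layers 0..L-1

  pieces <- list()
  for (k in seq_along(chains)) {
    for (i in seq_along(bases)) {
      resid <- paste0("D", bases[i])
      tpl <- .nt_templates[[resid]]
      xyz <- .place_template(tpl, k - 1L, layer[i], rise, twist_rad)
      pieces[[length(pieces) + 1L]] <-
        .atoms_df(rownames(tpl), xyz, resid, chains[k], i)
    }
  }
  gq_structure(do.call(rbind, pieces),
               notes = "idealized tetramolecular parallel GQ (unrefined)")
}
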