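# Residue chemistry tables used by the editing and detection operations.
# Heavy-atom names only; hydrogens are optional everywhere and ignored.
.base_atoms <- list(
  DA  = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DG  = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  BGM = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4", "BR"),
  DC  = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  "5CM" = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "C5A"),
  DT  = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
)

# Glycosidic nitrogen and its two base-ring neighbours (frame anchors).
.gly_atoms <- list(
  DA = c("N9", "C8", "C4"), DG = c("N9", "C8", "C4"), BGM = c("N9", "C8", "C4"),
  DC = c("N1", "C2", "C6"), "5CM" = c("N1", "C2", "C6"), DT = c("N1", "C2", "C6")
)

# Six-membered-ring atoms (used for 5mC placement and base-plane fits).
.ring6_atoms <- list(
  DA = c("C5", "C6", "N1", "C2", "N3", "C4"),
  DG = c("C5", "C6", "N1", "C2", "N3", "C4"),
  BGM = c("C5", "C6", "N1", "C2", "N3", "C4"),
  DC = c("N1", "C2", "N3", "C4", "C5", "C6"),
  "5CM" = c("N1", "C2", "N3", "C4", "C5", "C6"),
  DT = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# Purine ring atoms for tetrad plane fits (9 heavy atoms of the guanine
# bicyclic ring; O6/N2 substituents excluded).
.purine_ring_atoms <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")

.guanine_resnames <- c("DG", "BGM")

.element_of <- function(name) {
  n <- toupper(gsub("[0-9']", "", name))
  if (n %in% c("BR")) return("Br")
  if (n == "") return("X")
  substr(n, 1, 1)
}

#' Construct an atomic GQ structure
#'
#' A `gq_structure` is a flat atom table (one row per atom) with residue and
#' chain bookkeeping, the container for all model building and editing in
#' this package.  Residues run 5' to 3' with ascending `resno` within each
#' chain.
#'
#' @param atom `data.frame` with columns `elety` (atom name), `resid`
#'   (residue name), `chain`, `resno`, `x`, `y`, `z` and optionally `elesy`
#'   (element symbol), `o`, `b`.
#' @param junctions Optional `data.frame` of recorded inter-strand bonds.
#' @param notes Character vector of free-form provenance notes.
#' @return An object of class `gq_structure`.
#' @export
gq_structure <- function(atom, junctions = NULL, notes = character()) {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  stopifnot(is.data.frame(atom), all(need %in% names(atom)))
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite atomic coordinates")
  if (is.null(atom$elesy))
    atom$elesy <- vapply(atom$elety, .element_of, character(1))
  if (is.null(atom$o)) atom$o <- 1
  if (is.null(atom$b)) atom$b <- 0
  key <- paste(atom$chain, atom$resno, atom$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom name) keys")
  atom$eleno <- seq_len(nrow(atom))
  rownames(atom) <- NULL
  structure(list(atom = atom, junctions = junctions, notes = notes),
            class = "gq_structure")
}

#' @export
print.gq_structure <- function(x, ...) {
  at <- x$atom
  cat(sprintf("<gq_structure> %d atoms, %d residues, chains: %s\n",
              nrow(at), nrow(unique(at[, c("chain", "resno")])),
              paste(unique(at$chain), collapse = ", ")))
  if (!is.null(x$junctions) && nrow(x$junctions))
    cat(sprintf("  %d recorded strand junction(s), max gap %.2f A\n",
                nrow(x$junctions), max(x$junctions$gap_A)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

# xyz matrix (n x 3) of a structure or an atom-table subset
.coords <- function(at) as.matrix(at[, c("x", "y", "z"), drop = FALSE])

# one atom's coordinates within a residue subset; NULL if absent
.atom_xyz <- function(at, name) {
  i <- which(at$elety == name)
  if (!length(i)) return(NULL)
  c(at$x[i[1]], at$y[i[1]], at$z[i[1]])
}

# residue keys in 5'->3' order (chain, then resno)
.residue_table <- function(s) {
  u <- unique(s$atom[, c("chain", "resno", "resid")])
  u[order(u$chain, u$resno), , drop = FALSE]
}

.res_atoms <- function(s, chain, resno) {
  s$atom[s$atom$chain == chain & s$atom$resno == resno, , drop = FALSE]
}

#' Read a PDB file into a `gq_structure`
#'
#' Thin wrapper around [bio3d::read.pdb()]; keeps ATOM and HETATM records of
#' the first model.
#'
#' @param path PDB file path.
#' @return A [gq_structure].
#' @export
read_gq_pdb <- function(path) {
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  at$chain[is.na(at$chain)] <- "A"
  gq_structure(data.frame(elety = at$elety, resid = at$resid, chain = at$chain,
                          resno = at$resno, x = at$x, y = at$y, z = at$z,
                          elesy = at$elesy, o = at$o, b = at$b,
                          stringsAsFactors = FALSE))
}

#' Write a `gq_structure` to a PDB file
#'
#' @param s A [gq_structure].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gq_pdb <- function(s, path) {
  stopifnot(inherits(s, "gq_structure"))
  at <- s$atom
  bio3d::write.pdb(file = path, xyz = as.vector(t(.coords(at))),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, o = at$o, b = at$b, elesy = at$elesy)
  invisible(path)
}

#' Delete residues from a structure
#'
#' Removes all atoms of the selected residues.  The numbering of the
#' remaining residues is left untouched (renumbering is a separate, explicit
#' step in [join_strands()]).
#'
#' @param s A [gq_structure].
#' @param resno Residue numbers to delete.
#' @param chain Chains to restrict the selection to; `NULL` (default) means
#'   every chain.
#' @return The edited [gq_structure].
#' @export
delete_residues <- function(s, resno, chain = NULL) {
  stopifnot(inherits(s, "gq_structure"))
  if (!length(resno)) return(s)
  sel <- s$atom$resno %in% resno
  if (!is.null(chain)) sel <- sel & s$atom$chain %in% chain
  if (!any(sel))
    stop("selection error: no residues match the given selection")
  gq_structure(s$atom[!sel, , drop = FALSE], s$junctions, s$notes)
}

# rotation taking orthonormal frame (u1,u2,u3) onto (v1,v2,v3): R = V U^T
.frame_rotation <- function(U, V) V %*% t(U)

.unit <- function(v) v / sqrt(sum(v^2))

# orthonormal triad from glycosidic anchors: origin N; e1 toward C1';
# e3 = base-plane normal from the two ring neighbours; e2 completes.
.glycosidic_frame <- function(n_xyz, c1_xyz, nb1_xyz, nb2_xyz) {
  e1 <- .unit(c1_xyz - n_xyz)
  e3 <- .unit(.cross3(nb1_xyz - n_xyz, nb2_xyz - n_xyz))
  e2 <- .unit(.cross3(e3, e1))
  e3 <- .cross3(e1, e2)
  cbind(e1, e2, e3)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Mutate a nucleotide base in place
#'
#' Replaces the base atoms of one residue with an idealized template of the
#' target base, aligned on the glycosidic frame (C1', the glycosidic
#' nitrogen, and its base-ring neighbours); the sugar-phosphate atoms are
#' kept at their original coordinates.  Mutating a residue to its own base
#' is the identity.  The special case 8-bromo-dG (`BGM`) to `DG` simply
#' removes the bromine and renames the residue, leaving the C8 position
#' untouched.
#'
#' @param s A [gq_structure].
#' @param chain,resno Residue to mutate.
#' @param target Target base name, one of `"DA"`, `"DC"`, `"DG"`, `"DT"`.
#' @return The edited [gq_structure].
#' @export
mutate_base <- function(s, chain, resno, target) {
  stopifnot(inherits(s, "gq_structure"))
  if (!target %in% c("DA", "DC", "DG", "DT"))
    stop("template error: unknown target base ", target)
  res <- .res_atoms(s, chain, resno)
  if (!nrow(res)) stop("selection error: residue not found")
  from <- res$resid[1]
  if (!from %in% names(.base_atoms))
    stop("template error: residue ", from, " has no base template")
  sel <- s$atom$chain == chain & s$atom$resno == resno
  if (from == target) return(s)
  if (from == "BGM" && target == "DG") {
    at <- s$atom[!(sel & s$atom$elety == "BR"), , drop = FALSE]
    at$resid[at$chain == chain & at$resno == resno] <- "DG"
    return(gq_structure(at, s$junctions, s$notes))
  }
  g_old <- .gly_atoms[[from]]
  anchors <- lapply(c(g_old, "C1'"), function(a) .atom_xyz(res, a))
  if (any(vapply(anchors, is.null, logical(1))))
    stop("connectivity error: residue lacks glycosidic frame atoms (",
         paste(c(g_old, "C1'"), collapse = ", "), ")")
  Vr <- .glycosidic_frame(anchors[[1]], anchors[[4]], anchors[[2]], anchors[[3]])

  tpl <- .nt_templates[[target]]
  g_new <- .gly_atoms[[target]]
  Vt <- .glycosidic_frame(tpl[g_new[1], ], tpl["C1'", ],
                          tpl[g_new[2], ], tpl[g_new[3], ])
  R <- .frame_rotation(Vt, Vr)
  base_new <- tpl[.base_atoms[[target]], , drop = FALSE]
  xyz_new <- sweep(base_new, 2, tpl[g_new[1], ]) %*% t(R)
  xyz_new <- sweep(xyz_new, 2, anchors[[1]], "+")

  keep <- s$atom[!(sel & s$atom$elety %in% .base_atoms[[from]]), , drop = FALSE]
  keep$resid[keep$chain == chain & keep$resno == resno] <- target
  add <- data.frame(elety = rownames(base_new), resid = target, chain = chain,
                    resno = resno, x = xyz_new[, 1], y = xyz_new[, 2],
                    z = xyz_new[, 3],
                    elesy = vapply(rownames(base_new), .element_of, character(1)),
                    o = 1, b = 0, eleno = 0, stringsAsFactors = FALSE)
  at <- rbind(keep, add)
  at <- at[order(at$chain, at$resno), , drop = FALSE]   # stable: residues contiguous
  gq_structure(at, s$junctions, s$notes)
}

#' Append a nucleotide at a chain's 3' end
#'
#' Adds one template nucleotide after the 3'-terminal residue, placing its
#' 5' phosphate 1.60 A along the C3'-O3' bond direction and orienting the
#' template so its P-O5' bond continues that direction.  The geometry is
#' template-internal and flagged `"unrefined"`: no minimization is done.
#'
#' @param s A [gq_structure].
#' @param chain Chain to extend.
#' @param base Base name of the appended residue (`"DC"`, ...).
#' @return The edited [gq_structure].
#' @export
append_residue_3prime <- function(s, chain, base = "DC") {
  stopifnot(inherits(s, "gq_structure"))
  if (!base %in% names(.nt_templates))
    stop("template error: unknown base ", base)
  ch <- s$atom[s$atom$chain == chain, , drop = FALSE]
  if (!nrow(ch)) stop("selection error: chain ", chain, " not found")
  last <- max(ch$resno)
  res <- ch[ch$resno == last, , drop = FALSE]
  o3 <- .atom_xyz(res, "O3'")
  c3 <- .atom_xyz(res, "C3'")
  if (is.null(o3) || is.null(c3))
    stop("connectivity error: 3'-terminal residue lacks O3'/C3'")
  d <- .unit(o3 - c3)
  p_pos <- o3 + 1.60 * d

  tpl <- .nt_templates[[base]]
  v_t <- .unit(tpl["O5'", ] - tpl["P", ])
  # minimal rotation taking the template P->O5' direction onto d
  axis <- .cross3(v_t, d)
  sn <- sqrt(sum(axis^2)); cs <- sum(v_t * d)
  R <- if (sn < 1e-12) {
    if (cs > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - cs) / sn^2)
  }
  xyz <- sweep(tpl, 2, tpl["P", ]) %*% t(R)
  xyz <- sweep(xyz, 2, p_pos, "+")
  add <- data.frame(elety = rownames(tpl), resid = base, chain = chain,
                    resno = last + 1L, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    elesy = vapply(rownames(tpl), .element_of, character(1)),
                    o = 1, b = 0, eleno = 0, stringsAsFactors = FALSE)
  at <- rbind(s$atom, add)
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  gq_structure(at, s$junctions, c(s$notes, sprintf(
    "appended %s at 3' end of chain %s (unrefined template geometry)", base, chain)))
}

#' Join strands into a single continuous oligonucleotide
#'
#' Concatenates the chains in the given 5'-to-3' order into one chain,
#' renumbering residues 1..N.  Each junction (3'-O3' of one strand to 5'-P
#' of the next) is recorded with its gap distance in the `junctions` table;
#' the geometry is not minimized, so gaps report how far the unrefined ends
#' sit from bonding distance.
#'
#' @param s A [gq_structure].
#' @param order Chain identifiers in joining order.
#' @param new_chain Chain id of the joined molecule.
#' @return The edited [gq_structure] with a `junctions` table
#'   (`from_chain`, `to_chain`, `o3_resno`, `p_resno`, `gap_A`).
#' @export
join_strands <- function(s, order = sort(unique(s$atom$chain)), new_chain = "A") {
  stopifnot(inherits(s, "gq_structure"))
  if (!all(order %in% s$atom$chain))
    stop("selection error: unknown chain in joining order")
  pieces <- list(); junc <- NULL; counter <- 0L
  for (ci in seq_along(order)) {
    ch <- s$atom[s$atom$chain == order[ci], , drop = FALSE]
    ch <- ch[order(ch$resno), , drop = FALSE]
    old <- unique(ch$resno)
    map <- stats::setNames(seq_along(old) + counter, old)
    ch$resno <- map[as.character(ch$resno)]
    ch$chain <- new_chain
    counter <- counter + length(old)
    pieces[[ci]] <- ch
    if (ci > 1L) {
      prev <- pieces[[ci - 1L]]
      o3 <- .atom_xyz(prev[prev$resno == max(prev$resno), , drop = FALSE], "O3'")
      p5 <- .atom_xyz(ch[ch$resno == min(ch$resno), , drop = FALSE], "P")
      if (is.null(o3) || is.null(p5))
        stop("connectivity error: junction ", order[ci - 1L], "->", order[ci],
             " lacks O3' or P")
      junc <- rbind(junc, data.frame(
        from_chain = order[ci - 1L], to_chain = order[ci],
        o3_resno = max(prev$resno), p_resno = min(ch$resno),
        gap_A = sqrt(sum((o3 - p5)^2))))
    }
  }
  gq_structure(do.call(rbind, pieces), junctions = junc,
               notes = c(s$notes, sprintf("joined %d strand(s) into chain %s",
                                          length(order), new_chain)))
}

#' Add 5-methylcytosine methyl groups at CpG cytosines
#'
#' For each selected cytosine the methyl carbon (`C5A`) is placed in the
#' base plane, 1.50 A from C5 along the direction pointing away from the
#' six-membered-ring centroid, and the residue is renamed `5CM`.  Each
#' selected residue must be a `DC` whose 3' neighbour in the same chain is a
#' guanine (CpG context).
#'
#' @param s A [gq_structure].
#' @param resno Residue numbers of the cytosines to methylate, or an
#'   [oligo_seq] whose `methyl` flags select them (residue `i` of the single
#'   chain corresponds to sequence position `i - 1`).
#' @param chain Chain the residues live in (default: the only chain).
#' @return The edited [gq_structure].
#' @export
add_methyl_cpg <- function(s, resno, chain = NULL) {
  stopifnot(inherits(s, "gq_structure"))
  if (inherits(resno, "oligo_seq")) resno <- which(resno$methyl)
  if (!length(resno)) return(s)
  if (is.null(chain)) {
    chains <- unique(s$atom$chain)
    if (length(chains) != 1L)
      stop("multiple chains present: specify `chain`")
    chain <- chains
  }
  at <- s$atom
  for (rn in resno) {
    res <- .res_atoms(s, chain, rn)
    if (!nrow(res) || res$resid[1] != "DC")
      stop("invalid site: residue ", rn, " is not a DC")
    nxt <- .res_atoms(s, chain, rn + 1L)
    if (!nrow(nxt) || !nxt$resid[1] %in% .guanine_resnames)
      stop("invalid site: residue ", rn, " is not in CpG context")
    ring <- res[res$elety %in% .ring6_atoms$DC, , drop = FALSE]
    if (nrow(ring) != 6L)
      stop("invalid site: residue ", rn, " lacks complete ring atoms")
    X <- .coords(ring)
    ctr <- colMeans(X)
    sv <- svd(sweep(X, 2, ctr))
    nrm <- sv$v[, 3]
    c5 <- .atom_xyz(res, "C5")
    u <- c5 - ctr
    u <- u - sum(u * nrm) * nrm          # project into the ring plane
    pos <- c5 + 1.50 * .unit(u)
    sel <- at$chain == chain & at$resno == rn
    at$resid[sel] <- "5CM"
    at <- rbind(at, data.frame(elety = "C5A", resid = "5CM", chain = chain,
                               resno = rn, x = pos[1], y = pos[2], z = pos[3],
                               elesy = "C", o = 1, b = 0, eleno = 0,
                               stringsAsFactors = FALSE))
  }
  ord <- order(at$chain, at$resno, at$elety %in% "C5A")
  gq_structure(at[ord, , drop = FALSE], s$junctions, s$notes)
}

#' Count non-bonded heavy-atom clashes
#'
#' Number of heavy-atom pairs from different residues closer than
#' `threshold`; the bonded O3'(i)-P(i+1) backbone junction of consecutive
#' residues in a chain is excluded.  A crude steric sanity check for
#' unminimized edited models.
#'
#' @param s A [gq_structure].
#' @param threshold Distance threshold in Angstrom (default 2.0).
#' @return Integer clash count.
#' @export
count_clashes <- function(s, threshold = 2.0) {
  stopifnot(inherits(s, "gq_structure"))
  at <- s$atom[s$atom$elesy != "H", , drop = FALSE]
  if (nrow(at) < 2L) return(0L)
  D <- as.matrix(stats::dist(.coords(at)))
  close <- which(D < threshold & upper.tri(D), arr.ind = TRUE)
  if (!nrow(close)) return(0L)
  n <- 0L
  for (k in seq_len(nrow(close))) {
    i <- close[k, 1]; j <- close[k, 2]
    same_res <- at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]
    if (same_res) next
    bonded <- at$chain[i] == at$chain[j] &&
      ((at$resno[j] - at$resno[i] == 1L && at$elety[i] == "O3'" && at$elety[j] == "P") ||
       (at$resno[i] - at$resno[j] == 1L && at$elety[j] == "O3'" && at$elety[i] == "P"))
    if (!bonded) n <- n + 1L
  }
  n
}
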