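# Total-least-squares plane through a point set: returns list(centroid,
# normal) with |normal| = 1 (third right-singular vector).
.fit_plane <- function(X) {
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Detect Hoogsteen guanine tetrads
#'
#' Finds planar G-quartets as directed 4-cycles of guanine residues in which
#' each guanine's Watson-Crick edge donors reach the next guanine's
#' Hoogsteen-edge acceptors: `N1(i)...O6(i+1)` and `N2(i)...N7(i+1)` both
#' within `cutoff`.  Heavy-atom donor-acceptor distances are used (no
#' hydrogen geometry), so detection works on heavy-atom-only models.  When
#' candidate quartets share residues, quartets are accepted greedily by
#' ascending total donor-acceptor distance.
#'
#' Each tetrad carries a total-least-squares plane over the 4 x 9 purine
#' ring atoms and a `stack_index`: tetrad centroids are projected on the
#' stack axis (first principal component of the centroids), oriented so the
#' tetrad containing the 5'-most guanine has index 0.
#'
#' @param s A [gq_structure].
#' @param cutoff Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @return List of tetrads (class `gq_tetrads`), each a list with
#'   `residues` (data.frame `chain`, `resno` in cyclic order), `centroid`,
#'   `normal`, `stack_index`, `hbond_dists`.  Empty list if none found.
#' @examples
#' gq <- build_ideal_gq(expand_repeat("GGGGCC", 3, "GGGG"))
#' length(detect_tetrads(gq))  # 4
#' @export
detect_tetrads <- function(s, cutoff = 3.5) {
  stopifnot(inherits(s, "gq_structure"))
  rt <- .residue_table(s)
  gres <- rt[rt$resid %in% .guanine_resnames, , drop = FALSE]
  n <- nrow(gres)
  empty <- structure(list(), class = "gq_tetrads")
  if (n < 4L) return(empty)

  need <- c("N1", "N2", "O6", "N7")
  coords <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- .res_atoms(s, gres$chain[i], gres$resno[i])
    xs <- lapply(need, function(a) .atom_xyz(res, a))
    ok[i] <- !any(vapply(xs, is.null, logical(1)))
    if (ok[i]) coords[[i]] <- stats::setNames(xs, need)
  }
  idx <- which(ok)
  if (length(idx) < 4L) return(empty)

  # directed Hoogsteen adjacency and its distance weight
  m <- length(idx)
  adj <- matrix(FALSE, m, m)
  wt <- matrix(Inf, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    d1 <- sqrt(sum((coords[[idx[a]]]$N1 - coords[[idx[b]]]$O6)^2))
    d2 <- sqrt(sum((coords[[idx[a]]]$N2 - coords[[idx[b]]]$N7)^2))
    if (d1 <= cutoff && d2 <= cutoff) {
      adj[a, b] <- TRUE
      wt[a, b] <- d1 + d2
    }
  }

  # enumerate directed 4-cycles, canonical start = smallest member
  cand <- list()
  for (a in seq_len(m)) for (b in which(adj[a, ])) {
    if (b <= a) next
    for (cc in which(adj[b, ])) {
      if (cc == a || cc <= a) next
      for (d in which(adj[cc, ])) {
        if (d <= a || d == b || d == cc || !adj[d, a]) next
        cyc <- c(a, b, cc, d)
        cand[[length(cand) + 1L]] <-
          list(cyc = cyc, w = wt[a, b] + wt[b, cc] + wt[cc, d] + wt[d, a])
      }
    }
  }
  if (!length(cand)) return(empty)
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "w"))]
  used <- integer(0)
  picked <- list()
  for (cn in cand) {
    if (any(cn$cyc %in% used)) next
    picked[[length(picked) + 1L]] <- cn$cyc
    used <- c(used, cn$cyc)
  }

  tetrads <- lapply(picked, function(cyc) {
    gi <- idx[cyc]
    rings <- do.call(rbind, lapply(gi, function(i) {
      res <- .res_atoms(s, gres$chain[i], gres$resno[i])
      .coords(res[res$elety %in% .purine_ring_atoms, , drop = FALSE])
    }))
    pl <- .fit_plane(rings)
    list(residues = data.frame(chain = gres$chain[gi], resno = gres$resno[gi],
                               stringsAsFactors = FALSE),
         centroid = pl$centroid, normal = pl$normal, stack_index = NA_integer_,
         hbond_dists = c(wt[cyc[1], cyc[2]], wt[cyc[2], cyc[3]],
                         wt[cyc[3], cyc[4]], wt[cyc[4], cyc[1]]) / 2)
  })

  # stack ordering along the principal axis of the centroids
  if (length(tetrads) >= 2L) {
    C <- do.call(rbind, lapply(tetrads, `[[`, "centroid"))
    axis <- svd(sweep(C, 2, colMeans(C)))$v[, 1]
    proj <- as.vector(sweep(C, 2, colMeans(C)) %*% axis)
    five_most <- which.min(vapply(tetrads, function(tt)
      min(tt$residues$resno), numeric(1)))
    if (proj[five_most] > stats::median(proj)) { axis <- -axis; proj <- -proj }
    ord <- order(proj)
    tetrads <- tetrads[ord]
    for (k in seq_along(tetrads)) {
      tetrads[[k]]$stack_index <- k - 1L
      if (sum(tetrads[[k]]$normal * axis) < 0)
        tetrads[[k]]$normal <- -tetrads[[k]]$normal
    }
  } else if (length(tetrads) == 1L) {
    tetrads[[1]]$stack_index <- 0L
  }
  structure(tetrads, class = "gq_tetrads")
}

#' @export
print.gq_tetrads <- function(x, ...) {
  cat(sprintf("<gq_tetrads> %d tetrad(s)\n", length(x)))
  for (tt in x)
    cat(sprintf("  [%d] residues %s, mean H-bond %.2f A\n", tt$stack_index,
                paste(paste0(tt$residues$chain, tt$residues$resno), collapse = "-"),
                mean(tt$hbond_dists)))
  invisible(x)
}

#' Place potassium ions between stacked tetrads
#'
#' Adds one K+ per adjacent tetrad pair, at the midpoint of the two
#' tetrads' O6 centroids (the carbonyl cage that coordinates the ion in
#' real GQs).  `n - 1` ions are placed for `n` tetrads.
#'
#' @param s A [gq_structure].
#' @param tetrads Tetrads from [detect_tetrads()], stack-ordered.
#' @return The [gq_structure] with K ions appended (chain `"I"`, residue
#'   name `K`).
#' @export
place_interplane_ions <- function(s, tetrads) {
  stopifnot(inherits(s, "gq_structure"))
  if (length(tetrads) < 2L) {
    warning("fewer than 2 tetrads: no inter-plane ions placed")
    return(s)
  }
  o6_centroid <- function(tt) {
    X <- do.call(rbind, lapply(seq_len(4), function(k) {
      res <- .res_atoms(s, tt$residues$chain[k], tt$residues$resno[k])
      .atom_xyz(res, "O6")
    }))
    colMeans(X)
  }
  cents <- lapply(tetrads, o6_centroid)
  at <- s$atom
  for (k in seq_len(length(tetrads) - 1L)) {
    pos <- (cents[[k]] + cents[[k + 1L]]) / 2
    at <- rbind(at, data.frame(elety = "K", resid = "K", chain = "I",
                               resno = k, x = pos[1], y = pos[2], z = pos[3],
                               elesy = "K", o = 1, b = 0, eleno = 0,
                               stringsAsFactors = FALSE))
  }
  gq_structure(at, s$junctions,
               c(s$notes, sprintf("placed %d inter-tetrad K+ ion(s)",
                                  length(tetrads) - 1L)))
}
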