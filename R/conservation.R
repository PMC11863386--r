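#' Structure entry for triad-anchored superposition
#'
#' @param id structure identifier.
#' @param atoms data.frame with `atom_name`, `residue_id`,
#'   `residue_name`, `x`, `y`, `z` (Angstrom).
#' @param triad_anchor integer row indices (into `atoms`) of the
#'   catalytic-His side-chain atoms used as the alignment anchor.
#' @return an object of class `structure_entry`.
#' @export
structure_entry <- function(id, atoms, triad_anchor) {
  stopifnot(is.data.frame(atoms),
            all(c("atom_name", "residue_id", "x", "y", "z") %in%
                  names(atoms)),
            length(triad_anchor) >= 3,
            all(triad_anchor %in% seq_len(nrow(atoms))))
  if (any(!is.finite(as.matrix(atoms[triad_anchor, c("x", "y", "z")])))) {
    stop("anchor atoms must have finite coordinates")
  }
  structure(list(id = id, atoms = atoms,
                 triad_anchor = as.integer(triad_anchor)),
            class = "structure_entry")
}

#' Read a PDB file into a structure entry
#'
#' Coordinates are parsed with `bio3d`; the anchor defaults to the
#' side-chain atoms of the given histidine residue (ring atoms CB, CG,
#' ND1, CD2, CE1, NE2, configurable).
#'
#' @param path PDB file.
#' @param id identifier; defaults to the file name.
#' @param his_resno residue number of the catalytic His.
#' @param anchor_atoms atom names anchoring the superposition.
#' @return a [structure_entry()].
#' @export
read_structure_pdb <- function(path, id = basename(path), his_resno,
                               anchor_atoms = c("CB", "CG", "ND1",
                                                "CD2", "CE1", "NE2")) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  atoms <- data.frame(atom_name = a$elety, residue_id = a$resno,
                      residue_name = a$resid, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  anchor <- which(atoms$residue_id == his_resno &
                    atoms$atom_name %in% anchor_atoms)
  if (length(anchor) < 3) {
    stop("catalytic His anchor atoms not found in ", id)
  }
  structure_entry(id, atoms, anchor)
}

# Kabsch least-squares rigid superposition of point sets (rows).
# Returns rotation (proper, det = +1) and translation such that
# mobile %*% R + t approximates reference.
.kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t <- cr - drop(cm %*% R)
  list(R = R, t = t)
}

#' Superpose a structure onto a reference by the triad anchor
#'
#' Least-squares optimal rigid transform (Kabsch, proper rotation with
#' det = +1) fitted on the anchor atoms and applied to all atoms of the
#' mobile structure. The RMSD is reported over the anchor atoms only.
#'
#' @param mobile,reference [structure_entry()] objects whose anchors
#'   have equal atom count and matching order.
#' @return list with the transformed `structure` (a `structure_entry`),
#'   `rmsd` (Angstrom over anchors), and the `rotation` and
#'   `translation` applied.
#' @export
superpose <- function(mobile, reference) {
  stopifnot(inherits(mobile, "structure_entry"),
            inherits(reference, "structure_entry"))
  if (length(mobile$triad_anchor) != length(reference$triad_anchor)) {
    stop("anchor atom counts differ (correspondence error)")
  }
  M <- as.matrix(mobile$atoms[mobile$triad_anchor, c("x", "y", "z")])
  R <- as.matrix(reference$atoms[reference$triad_anchor,
                                 c("x", "y", "z")])
  fit <- .kabsch(M, R)
  xyz <- as.matrix(mobile$atoms[c("x", "y", "z")]) %*% fit$R
  xyz <- sweep(xyz, 2, fit$t, `+`)
  out <- mobile
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  Mt <- xyz[mobile$triad_anchor, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((Mt - R)^2)))
  list(structure = out, rmsd = rmsd, rotation = fit$R,
       translation = fit$t)
}

# proxy-atom map: one atom per charged residue type locates its formal
# charge in space
.proxy_map <- data.frame(
  residue_name = c("LYS", "ARG", "ASP", "GLU"),
  proxy_atom = c("NZ", "CZ", "CG", "CD"),
  sign = c("+", "+", "-", "-"),
  stringsAsFactors = FALSE
)

#' Collect charge-proxy atoms from superposed structures
#'
#' One proxy per qualifying charged residue: Lys NZ and Arg CZ locate
#' positive charges, Asp CG and Glu CD negative charges. Catalytic
#' residues are excluded by residue id.
#'
#' @param structures list of superposed [structure_entry()] objects in
#'   one common frame.
#' @param exclusions residue ids of catalytic residues to skip.
#' @return data.frame with `structure_id`, `residue_id`,
#'   `residue_name`, `sign`, `x`, `y`, `z`.
#' @export
collect_proxies <- function(structures, exclusions = integer(0)) {
  out <- lapply(structures, function(s) {
    a <- s$atoms
    m <- merge(a, .proxy_map,
               by.x = c("residue_name", "atom_name"),
               by.y = c("residue_name", "proxy_atom"))
    m <- m[!(m$residue_id %in% exclusions), , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    data.frame(structure_id = s$id, residue_id = m$residue_id,
               residue_name = m$residue_name, sign = m$sign,
               x = m$x, y = m$y, z = m$z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(structure_id = character(0),
                      residue_id = integer(0),
                      residue_name = character(0), sign = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Cluster charge proxies into conserved sites
#'
#' Single-linkage radius clustering per charge sign (equivalent to
#' connected components of the graph linking proxies closer than
#' `radius`). Sites supported by at least `min_occupancy` of the
#' structures are retained and sorted by distance to `query_point`
#' when given (e.g. the triad centroid).
#'
#' @param proxies data.frame from [collect_proxies()].
#' @param radius linkage radius, Angstrom.
#' @param min_occupancy minimum fraction of structures contributing.
#' @param n_structures total number of structures (denominator of the
#'   occupancy); defaults to the distinct structures present.
#' @param query_point optional length-3 point for sorting.
#' @return data.frame with `sign`, `x`, `y`, `z` (centroid),
#'   `member_count`, `occupancy`.
#' @export
cluster_sites <- function(proxies, radius = 2.5, min_occupancy = 0,
                          n_structures = NULL, query_point = NULL) {
  stopifnot(radius > 0)
  if (nrow(proxies) == 0) {
    return(data.frame(sign = character(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      member_count = integer(0), occupancy = numeric(0)))
  }
  if (is.null(n_structures)) {
    n_structures <- length(unique(proxies$structure_id))
  }
  res <- lapply(split(proxies, proxies$sign), function(p) {
    xyz <- as.matrix(p[c("x", "y", "z")])
    cl <- if (nrow(p) == 1) 1L else {
      stats::cutree(stats::hclust(stats::dist(xyz), method = "single"),
                    h = radius)
    }
    do.call(rbind, lapply(split(seq_len(nrow(p)), cl), function(idx) {
      data.frame(sign = p$sign[1],
                 x = mean(xyz[idx, 1]), y = mean(xyz[idx, 2]),
                 z = mean(xyz[idx, 3]),
                 member_count = length(idx),
                 occupancy = length(unique(p$structure_id[idx])) /
                   n_structures)
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- out[out$occupancy >= min_occupancy, , drop = FALSE]
  if (!is.null(query_point)) {
    d <- sqrt((out$x - query_point[1])^2 + (out$y - query_point[2])^2 +
                (out$z - query_point[3])^2)
    out <- out[order(d), , drop = FALSE]
    out$dist_to_query <- sort(d)
  }
  rownames(out) <- NULL
  out
}

#' Alignment-column conservation at reference positions
#'
#' Maps positions in the reference sequence's own numbering through the
#' alignment (gap-aware) to columns, and reports the percent frequency
#' of each residue per column. By default gap rows are excluded from
#' the denominator; columns counted over fewer than `min_support`
#' sequences are flagged low-support.
#'
#' @param alignment path to an aligned FASTA file, or a named character
#'   vector / `Biostrings::AAStringSet` of aligned sequences.
#' @param reference_seq_id name of the reference sequence.
#' @param reference_positions positions in reference numbering
#'   (ungapped).
#' @param count_gaps if `TRUE`, gap rows enter the denominator.
#' @param min_support minimum counted sequences before a low-support
#'   flag.
#' @return data.frame with `position`, `column`, `residue`, `percent`,
#'   `n_counted`, `low_support`. Percentages sum to 100 per column over
#'   the counted rows.
#' @export
column_conservation <- function(alignment, reference_seq_id,
                                reference_positions,
                                count_gaps = FALSE, min_support = 2L) {
  seqs <- .as_aligned_strings(alignment)
  if (!reference_seq_id %in% names(seqs)) {
    stop("reference sequence '", reference_seq_id,
         "' not found in the alignment")
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  ref <- mat[reference_seq_id, ]
  ref_map <- cumsum(ref != "-")
  out <- lapply(reference_positions, function(p) {
    col <- match(p, ref_map)
    if (is.na(col) || ref[col] == "-") {
      stop("reference position ", p, " maps to a gap (mapping error)")
    }
    column <- mat[, col]
    counted <- if (count_gaps) column else column[column != "-"]
    n <- length(counted)
    tab <- table(counted)
    data.frame(position = p, column = col,
               residue = names(tab),
               percent = 100 * as.numeric(tab) / n,
               n_counted = n, low_support = n < min_support,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.as_aligned_strings <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    ss <- Biostrings::readAAStringSet(alignment)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
  } else if (inherits(alignment, "AAStringSet")) {
    seqs <- as.character(alignment)
    names(seqs) <- sub("\\s.*$", "", names(alignment))
  } else {
    seqs <- stats::setNames(as.character(alignment), names(alignment))
  }
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must share one length")
  }
  seqs
}

#' Greedy redundancy filter on aligned sequences
#'
#' Keeps sequences in input order, dropping any whose pairwise identity
#' to an already-kept sequence exceeds `max_identity`. Identity is the
#' fraction of identical residues over columns where both rows are
#' ungapped. A lightweight stand-in for external redundancy servers,
#' preserving the pipeline stage.
#'
#' @param alignment as in [column_conservation()].
#' @param max_identity identity threshold in (0, 1]; default 0.9.
#' @return named character vector of the retained aligned sequences.
#' @export
filter_redundant <- function(alignment, max_identity = 0.9) {
  seqs <- .as_aligned_strings(alignment)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- integer(0)
  for (i in seq_along(seqs)) {
    ok <- TRUE
    for (j in keep) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      if (sum(both) > 0 &&
          mean(mat[i, both] == mat[j, both]) > max_identity) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  seqs[keep]
}
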