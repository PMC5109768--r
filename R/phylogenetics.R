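# Reference-projection alignment, Kimura 2-parameter distances,
# neighbor-joining trees and column-resampling bootstrap.

#' Reference-projection multiple alignment
#'
#' Globally aligns each member against the reference (match +1, mismatch
#' -1, linear gap -2). Reference columns are shared directly; member
#' insertions relative to the reference open shared gap columns sized to
#' the longest insertion observed at that reference position. Members
#' below `min_identity` to the reference are excluded with a notice. The
#' procedure is deterministic, which is valid here because all monomers
#' share the XmnI phase and are nearly length-identical.
#'
#' @param members Named character vector of reference-oriented, XmnI-phase
#'   sequences.
#' @param reference Reference sequence.
#' @param min_identity Exclusion threshold (default 0.5).
#' @return Object of class `projection_alignment`: `ids` and `matrix`
#'   (members x columns character matrix).
#' @export
project_align <- function(members, reference, min_identity = 0.5) {
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  ids <- names(members)
  if (is.null(ids)) ids <- paste0("seq", seq_along(members))
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- pairwiseAlignment(DNAStringSet(members), DNAString(reference),
                          type = "global", substitutionMatrix = mat,
                          gapOpening = 0, gapExtension = 2)
  ident <- nmatch(pa) / nchar(pa)
  keep <- ident >= min_identity
  if (!all(keep)) {
    message(sum(!keep), " member(s) below ", min_identity,
            " identity to the reference excluded")
  }
  if (!any(keep)) stop("no member passes the identity threshold",
                       call. = FALSE)
  ids <- ids[keep]
  ap <- as.character(alignedPattern(pa))[keep]
  as_ <- as.character(alignedSubject(pa))[keep]
  L <- nchar(reference)
  # per member: characters over reference columns + insertions keyed by the
  # reference position after which they occur
  proj <- vector("list", length(ids))
  ins_max <- integer(L + 1L)  # insertions after ref position 0..L
  for (i in seq_along(ids)) {
    p <- seq_chars(ap[i]); s <- seq_chars(as_[i])
    refcols <- character(L)
    ins <- vector("list", L + 1L)
    rpos <- 0L
    buf <- character(0)
    for (j in seq_along(s)) {
      if (s[j] == "-") {
        buf <- c(buf, p[j])
      } else {
        if (length(buf)) {
          ins[[rpos + 1L]] <- buf
          ins_max[rpos + 1L] <- max(ins_max[rpos + 1L], length(buf))
          buf <- character(0)
        }
        rpos <- rpos + 1L
        refcols[rpos] <- p[j]
      }
    }
    if (length(buf)) {
      ins[[rpos + 1L]] <- buf
      ins_max[rpos + 1L] <- max(ins_max[rpos + 1L], length(buf))
    }
    proj[[i]] <- list(refcols = refcols, ins = ins)
  }
  ncols <- L + sum(ins_max)
  M <- matrix("-", nrow = length(ids), ncol = ncols,
              dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    col <- 0L
    for (r in 0:L) {
      if (ins_max[r + 1L] > 0L) {
        v <- proj[[i]]$ins[[r + 1L]]
        if (!is.null(v)) M[i, col + seq_along(v)] <- v
        col <- col + ins_max[r + 1L]
      }
      if (r < L) {
        col <- col + 1L
        M[i, col] <- proj[[i]]$refcols[r + 1L]
      }
    }
  }
  structure(list(ids = ids, matrix = M), class = "projection_alignment")
}

.TRANSITIONS <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)

#' Kimura 2-parameter distance between two aligned rows
#'
#' Sites with a gap or ambiguity in either row are excluded. With P the
#' transition and Q the transversion proportion over included sites,
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When a log argument is
#' non-positive the distance is saturated and returned as `NA` with a
#' warning.
#'
#' @param row_a,row_b Equal-length character vectors (or strings).
#' @return Distance (>= 0), or `NA_real_` on saturation.
#' @export
k2p_distance <- function(row_a, row_b) {
  if (length(row_a) == 1L && nchar(row_a[1]) > 1L) row_a <- seq_chars(row_a)
  if (length(row_b) == 1L && nchar(row_b[1]) > 1L) row_b <- seq_chars(row_b)
  stopifnot(length(row_a) == length(row_b))
  ok <- row_a %in% DNA_BASES & row_b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  a <- row_a[ok]; b <- row_b[ok]
  diff <- a != b
  ts <- diff & !is.na(.TRANSITIONS[paste0(a, b)])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    warning("K2P distance saturated", call. = FALSE)
    return(NA_real_)
  }
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' Pairwise K2P distance matrix from an alignment
#'
#' @param alignment A [project_align()] result or a character matrix.
#' @param deletion `"pairwise"` (default): gapped sites excluded per pair;
#'   `"global"`: columns with any gap/ambiguity dropped for all pairs.
#' @return Symmetric matrix (class `dist`-compatible, plain matrix) with
#'   zero diagonal; saturated entries are `NA`.
#' @export
k2p_matrix <- function(alignment, deletion = c("pairwise", "global")) {
  deletion <- match.arg(deletion)
  M <- if (inherits(alignment, "projection_alignment")) {
    alignment$matrix
  } else alignment
  if (deletion == "global") {
    keep <- apply(M, 2, function(col) all(col %in% DNA_BASES))
    M <- M[, keep, drop = FALSE]
  }
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- suppressWarnings(k2p_distance(M[i, ], M[j, ]))
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining on a distance matrix. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sibling edge. Saturated (`NA`) distances are an error.
#'
#' @param distances Symmetric numeric matrix with ids as dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (nrow(distances) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(is.na(distances)) || any(!is.finite(distances))) {
    stop("distance matrix contains saturated or non-finite entries",
         call. = FALSE)
  }
  tree <- ape::nj(as.dist(distances))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Column-resampling bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P/NJ tree
#' per replicate, and reports for every internal edge of the original tree
#' the percentage of replicates containing the same bipartition.
#' Replicates whose distance matrix contains saturated entries are dropped
#' (the support denominator is the number of usable replicates).
#'
#' @param alignment A [project_align()] result or character matrix.
#' @param n_reps Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param deletion Passed to [k2p_matrix()].
#' @return The original tree with integer `node.label` supports in
#'   [0, 100].
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = NULL,
                              deletion = "pairwise") {
  M <- if (inherits(alignment, "projection_alignment")) {
    alignment$matrix
  } else alignment
  if (nrow(M) < 4L) stop("need at least 4 members", call. = FALSE)
  tree0 <- nj_tree(k2p_matrix(M, deletion))
  trees <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      D <- k2p_matrix(M[, cols, drop = FALSE], deletion)
      if (any(is.na(D))) return(NULL)
      nj_tree(D)
    })
  })
  trees <- trees[!vapply(trees, is.null, TRUE)]
  if (length(trees) == 0L) stop("all bootstrap replicates saturated",
                                call. = FALSE)
  counts <- ape::prop.clades(tree0, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree0$node.label <- as.integer(round(100 * counts / length(trees)))
  tree0
}
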