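# Alignment-free family discovery: 5-mer profiles -> PCA -> Ward HCA on a
# training subset -> linear discriminant extension to all sequences.

#' 5-mer composition profiles
#'
#' Counts all overlapping k-mers on the given strand (sequences are assumed
#' pre-oriented) and normalizes by the number of counted windows, so each
#' profile sums to 1. Windows containing ambiguous bases are skipped.
#'
#' @param seqs Character vector or `DNAStringSet` of sequences (length >= k).
#' @param k Word size (default 5, giving 1024 features).
#' @return Numeric matrix (sequences x 4^k), rownames from `names(seqs)`.
#' @export
kmer_profile <- function(seqs, k = 5) {
  if (length(seqs) == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = 4^k))
  }
  ss <- DNAStringSet(seqs)
  if (any(Biostrings::width(ss) < k)) {
    stop("all sequences must be at least ", k, " bases long", call. = FALSE)
  }
  counts <- oligonucleotideFrequency(ss, width = k)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("some sequences have no unambiguous ", k, "-mer window",
         call. = FALSE)
  }
  prof <- counts / tot
  rownames(prof) <- if (!is.null(names(seqs))) names(seqs) else
    as.character(seq_along(seqs))
  prof
}

#' Fit a family model (PCA + Ward clustering + LDA)
#'
#' Principal component analysis on centered k-mer frequencies; Ward
#' agglomeration (`ward.D2`) on Euclidean distances in the retained PC
#' space of a seeded random training subset; the dendrogram is cut at `k`
#' clusters (or, in auto mode, at the k in 2..6 maximizing the mean
#' silhouette width, with silhouette distances evaluated in the leading-PC
#' subspace -- first `min(10, n_components)` PCs -- where between-family
#' structure concentrates, so the index is not diluted by noise
#' dimensions); a linear discriminant model is then trained on the
#' training PC scores with the cluster labels. Families are labeled
#' `F1, F2, ...` in decreasing training-size order.
#'
#' @param profiles Profile matrix from [kmer_profile()].
#' @param n_components Number of PCs retained (default 100; truncated with
#'   a notice when the data support fewer).
#' @param train_size Training subset size (default 2500; all profiles when
#'   fewer are available).
#' @param k Cluster count, or `"auto"` for the silhouette choice.
#' @param seed Integer seed for the training subset draw.
#' @return An object of class `family_model`.
#' @export
fit_family_model <- function(profiles, n_components = 100, train_size = 2500,
                             k = "auto", seed = NULL) {
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 profiles", call. = FALSE)
  if (all(apply(profiles, 2, function(x) diff(range(x))) == 0)) {
    stop("all profiles are identical: degenerate variance", call. = FALSE)
  }
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  nc <- min(n_components, rank, n - 1L, ncol(profiles))
  if (nc < n_components) {
    message("retaining ", nc, " components (requested ", n_components, ")")
  }
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  train_idx <- with_seed(seed, sample.int(n, min(train_size, n)))
  tr <- scores[train_idx, , drop = FALSE]
  d <- dist(tr)
  hc <- hclust(d, method = "ward.D2")
  if (identical(k, "auto")) {
    ks <- 2:min(6L, length(train_idx) - 1L)
    d_sil <- dist(tr[, seq_len(min(10L, nc)), drop = FALSE])
    sil <- vapply(ks, function(kk) {
      cl <- cutree(hc, kk)
      # a cut with a near-singleton cluster is not a usable family structure
      if (min(tabulate(cl, kk)) < 2L) return(-Inf)
      mean(cluster::silhouette(cl, d_sil)[, "sil_width"])
    }, 0)
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  cl <- if (k == 1L) rep(1L, length(train_idx)) else cutree(hc, k)
  # stable labels: F1 = largest training cluster
  ord <- order(tabulate(cl, k), decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- factor(paste0("F", relabel[cl]),
                   levels = paste0("F", seq_len(k)))
  lda_fit <- if (k > 1L) {
    suppressWarnings(MASS::lda(tr, grouping = labels))
  } else NULL
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(nc), drop = FALSE],
                 sdev = pc$sdev,
                 n_components = nc,
                 train_ids = rownames(profiles)[train_idx],
                 hclust = hc, k = k,
                 train_labels = labels,
                 lda = lda_fit,
                 family_levels = paste0("F", seq_len(k))),
            class = "family_model")
}

#' Project profiles onto a fitted model's PC space
#'
#' @param model A [fit_family_model()] result.
#' @param profiles Profile matrix.
#' @return Score matrix (sequences x retained components).
#' @export
project_profiles <- function(model, profiles) {
  if (ncol(profiles) != length(model$center)) {
    stop("profile dimension does not match the model", call. = FALSE)
  }
  sweep(profiles, 2, model$center) %*% model$rotation
}

#' Assign sequences to families with a fitted model
#'
#' Projects each profile onto the model's PC basis and scores it with the
#' linear discriminant; the assigned family is the posterior argmax.
#'
#' @param model A [fit_family_model()] result.
#' @param profiles Profile matrix from [kmer_profile()].
#' @return data.frame: `id`, `family`, plus one posterior column per family.
#' @export
assign_families <- function(model, profiles) {
  if (nrow(profiles) == 0L) {
    return(data.frame(id = character(0), family = character(0),
                      stringsAsFactors = FALSE))
  }
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(profiles)))
  if (model$k == 1L) {
    return(data.frame(id = ids, family = "F1", stringsAsFactors = FALSE))
  }
  scores <- project_profiles(model, profiles)
  pred <- predict(model$lda, scores)
  out <- data.frame(id = ids, family = as.character(pred$class),
                    stringsAsFactors = FALSE)
  post <- as.data.frame(pred$posterior)
  names(post) <- paste0("posterior_", names(post))
  cbind(out, post)
}

#' Best-permutation classification accuracy
#'
#' Accuracy of assigned labels against truth labels, maximized over label
#' permutations (cluster labels are arbitrary).
#'
#' @param assigned,truth Vectors of equal length.
#' @return Fraction in [0, 1].
#' @export
classification_accuracy <- function(assigned, truth) {
  stopifnot(length(assigned) == length(truth))
  a <- factor(assigned); t <- factor(truth)
  la <- levels(a); lt <- levels(t)
  if (length(la) > 7L) stop("too many labels for permutation search")
  # pad the smaller level set so permutations are well defined
  k <- max(length(la), length(lt))
  pad <- function(lv) c(lv, paste0(".pad", seq_len(k - length(lv)) + 0))[seq_len(k)]
  tab <- table(factor(a, levels = pad(la)), factor(t, levels = pad(lt)))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    hit <- sum(tab[cbind(seq_len(k), p)])
    if (hit > best) best <- hit
  }
  best / length(assigned)
}
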