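# Retrieval of candidate mathematical models: cosine similarity in the
# latent space, crop-scan target adjustment, and MAP@k scoring.

#' Cosine similarity between two embedding vectors
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return `dot(a,b) / (|a| |b|)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na < 1e-300 || nb < 1e-300) stop("zero-norm vector")
  clamp(sum(a * b) / (na * nb), -1, 1)
}

# Cosine similarities of one query against the rows of a matrix.
cosine_to_store <- function(query, vectors) {
  nq <- sqrt(sum(query^2))
  if (nq < 1e-300) stop("zero-norm query vector")
  nv <- sqrt(rowSums(vectors^2))
  if (any(nv < 1e-300)) stop("zero-norm vector in store")
  clamp(as.numeric(vectors %*% query) / (nv * nq), -1, 1)
}

#' Rank dataset rows by similarity to a query embedding
#'
#' Ties are broken by manifest order (stable sort), so rankings are
#' deterministic.
#'
#' @param query embedding vector.
#' @param store an `embedding_store`.
#' @param top_n number of rows to return; values above the store size are
#'   truncated with a warning.
#' @param exclude optional row indices to drop from the candidate list
#'   (e.g. the query itself when it is a store row).
#' @return a `similarity_ranking`: data.frame(row, model, score) ordered by
#'   descending score, with attributes `query_id` and `crop_ratio`.
#' @export
rank_similar <- function(query, store, top_n = 5L, exclude = integer(0)) {
  stopifnot(inherits(store, "embedding_store"))
  n <- nrow(store$vectors)
  if (n == 0L) stop("empty store")
  sc <- cosine_to_store(query, store$vectors)
  keep <- setdiff(seq_len(n), exclude)
  if (top_n > length(keep)) {
    warning("top_n exceeds store size; truncating")
    top_n <- length(keep)
  }
  ord <- keep[order(-sc[keep])]  # order() is stable: manifest order on ties
  ord <- ord[seq_len(top_n)]
  rk <- data.frame(row = ord, model = store$manifest$model[ord],
                   score = sc[ord], stringsAsFactors = FALSE)
  structure(rk, class = c("similarity_ranking", "data.frame"),
            crop_ratio = NA_real_)
}

#' Crop-scan model selection for a target image
#'
#' Encodes all 11 center-crop variants of the target (50%..100% in 5%
#' steps) and adopts the variant whose best match is strongest.
#'
#' @param target square image in \[0,1\] (already blurred/preprocessed).
#' @param store an `embedding_store`.
#' @param spec the [encoder_spec()] used for the store.
#' @param top_n rows to return for the adopted variant.
#' @param blur_sigma blur applied to each crop before encoding (match the
#'   store's preprocessing).
#' @return a `similarity_ranking` with attribute `crop_ratio` set to the
#'   adopted crop ratio.
#' @export
crop_scan_select <- function(target, store, spec = encoder_spec(),
                             top_n = 5L, blur_sigma = store$blur_sigma) {
  stopifnot(nrow(target) == ncol(target))
  crops <- center_crop_series(target, out_size = spec$input_size)
  best <- NULL
  best_ratio <- NA_real_
  for (cr in crops) {
    img <- if (blur_sigma > 0) blur(cr$image, blur_sigma) else cr$image
    v <- encode(img, spec)
    rk <- rank_similar(v, store, top_n = top_n)
    if (is.null(best) || rk$score[1] > best$score[1]) {
      best <- rk
      best_ratio <- cr$ratio
    }
  }
  attr(best, "crop_ratio") <- best_ratio
  best
}

#' Average precision at k for one ranking
#'
#' Mean of precision@i over the hit positions `i <= k`, normalized by the
#' number of positives within the top k (0 when there are none).  Set
#' `normalize = "k"` for the divide-by-k convention instead.
#'
#' @param ranking a `similarity_ranking` (query excluded from candidates).
#' @param positive_model model name counted as a hit.
#' @param k cutoff, `>= 1`.
#' @param normalize "hits" (positives within top k) or "k".
#' @return average precision in \[0, 1\].
#' @export
average_precision_at_k <- function(ranking, positive_model, k = 50L,
                                   normalize = c("hits", "k")) {
  normalize <- match.arg(normalize)
  stopifnot(k >= 1)
  lab <- utils::head(ranking$model, k) == positive_model
  if (!any(lab)) return(0)
  hits <- which(lab)
  prec <- cumsum(lab)[hits] / hits
  denom <- if (normalize == "hits") length(hits) else k
  sum(prec) / denom
}

#' MAP@k matrix across mathematical models
#'
#' Entry (i, j) is the mean, over store rows of model i used as queries, of
#' the average precision at k with model j as the positive class.  Each
#' query is excluded from its own candidate list.
#'
#' @param store an `embedding_store` covering >= 1 model.
#' @param k ranking cutoff (default 50).
#' @return square matrix with model names on both dimensions, entries in
#'   \[0, 1\].
#' @export
map_matrix <- function(store, k = 50L) {
  models <- sort(unique(store$manifest$model))
  stopifnot(length(models) >= 1)
  n <- nrow(store$vectors)
  kk <- min(k, n - 1L)
  ap <- matrix(0, length(models), length(models),
               dimnames = list(query = models, positive = models))
  cnt <- setNames(numeric(length(models)), models)
  for (q in seq_len(n)) {
    rk <- rank_similar(store$vectors[q, ], store, top_n = kk, exclude = q)
    m <- store$manifest$model[q]
    cnt[m] <- cnt[m] + 1
    for (pm in models) {
      ap[m, pm] <- ap[m, pm] + average_precision_at_k(rk, pm, k = kk)
    }
  }
  sweep(ap, 1, pmax(cnt, 1), "/")
}
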