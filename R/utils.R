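# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The six lesion diagnosis classes
#'
#' Returns the fixed class vocabulary used throughout the package, in the
#' order probabilities are reported: actinic keratosis (ACK), basal cell
#' carcinoma (BCC), melanoma (MEL), melanocytic nevus (NEV), squamous cell
#' carcinoma (SCC) and seborrheic keratosis (SEK).
#'
#' @return Character vector of length 6.
#' @export
lesion_classes <- function() c("ACK", "BCC", "MEL", "NEV", "SCC", "SEK")

# Coerce labels (character, factor or 1-based integer) to a factor over the
# six lesion classes; errors on unknown labels.
as_lesion_factor <- function(labels) {
  cls <- lesion_classes()
  if (is.numeric(labels)) {
    if (any(labels < 1 | labels > length(cls))) {
      stop("numeric labels must be in 1..", length(cls))
    }
    return(factor(cls[labels], levels = cls))
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), cls)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  factor(labels, levels = cls)
}

# Numerically stable softmax over a vector (max-subtraction).
softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise stable softmax of a matrix (loop-free row maxima; attention
# matrices are small but this sits on the training hot path).
softmax_rows <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  z <- exp(m - mx)
  z / rowSums(z)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

# Recursive map over a nested list of numeric arrays (parameter trees).
tree_map <- function(t, f) {
  if (is.list(t)) lapply(t, tree_map, f = f) else f(t)
}

# Recursive binary map over two parameter trees with identical shape.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(x, y, f), a, b)
    out
  } else {
    f(a, b)
  }
}

tree_sum <- function(t, f = identity) {
  if (is.list(t)) sum(vapply(t, tree_sum, numeric(1), f = f)) else sum(f(t))
}

# Flatten a parameter tree into one numeric vector (used by tests and
# parameter-count reporting); order is deterministic (list order).
tree_unlist <- function(t) unlist(t, use.names = FALSE)
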