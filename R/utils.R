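# internal numeric helpers

# row-wise log(sum(exp(x))) without overflow; column loop beats apply()
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  K <- ncol(m)
  if (K > 1L) for (k in 2L:K) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

# adjusted Fisher-Pearson moment skewness (the G1 estimator)
skewness_g1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# best-permutation agreement for class labels (K small, exhaustive)
perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    out[[i]] <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }
  do.call(rbind, out)
}

check_binary_items <- function(y) {
  bad <- !(y %in% c(0, 1) | is.na(y))
  if (any(bad)) {
    abort("symptom items must be 0, 1, or missing")
  }
}

# single place deciding which columns of a data frame are item columns
item_matrix <- function(data, items = NULL) {
  df <- as.data.frame(data)
  if (!is.null(items)) {
    missing_cols <- setdiff(items, names(df))
    if (length(missing_cols)) {
      abort(paste0("item columns not found: ", paste(missing_cols, collapse = ", ")))
    }
    df <- df[items]
  } else {
    keep <- vapply(df, is.numeric, logical(1)) &
      !names(df) %in% c("subject_id", ".true_class")
    df <- df[keep]
  }
  y <- as.matrix(df)
  check_binary_items(y)
  storage.mode(y) <- "double"
  y
}
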