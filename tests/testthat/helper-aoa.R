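# Brute-force area-of-applicability reference and toy predictor tables,
# shared by the applicability and acceptance tests.

# brute-force DI reference: double loop in explicitly constructed
# weighted/standardised space
brute_di <- function(data, spec, importances, newdata = NULL, fold = NULL) {
  num <- spec$numeric
  keep <- vapply(num, function(p) sd(data[[p]]) > 0, logical(1))
  num <- num[keep]
  w <- pmax(importances[c(num, spec$categorical)], 0)
  if (max(w) > 0) w <- w / max(w)
  emb <- function(d) {
    cols <- list()
    for (p in num) {
      cols[[p]] <- (d[[p]] - mean(data[[p]])) / sd(data[[p]]) * w[[p]]
    }
    for (p in spec$categorical) {
      for (l in sort(unique(as.character(data[[p]])))) {
        cols[[paste(p, l)]] <- as.numeric(as.character(d[[p]]) == l) * w[[p]]
      }
    }
    do.call(cbind, cols)
  }
  Tr <- emb(data)
  dsum <- 0; npair <- 0
  for (i in seq_len(nrow(Tr))) for (j in seq_len(nrow(Tr))) {
    if (j > i) { dsum <- dsum + sqrt(sum((Tr[i, ] - Tr[j, ])^2)); npair <- npair + 1 }
  }
  dbar <- dsum / npair
  if (is.null(newdata)) {
    vapply(seq_len(nrow(Tr)), function(i) {
      best <- Inf
      for (j in seq_len(nrow(Tr))) {
        if (j == i) next
        if (!is.null(fold) && fold[j] == fold[i]) next
        best <- min(best, sqrt(sum((Tr[i, ] - Tr[j, ])^2)))
      }
      best / dbar
    }, numeric(1))
  } else {
    Nw <- emb(newdata)
    vapply(seq_len(nrow(Nw)), function(i) {
      min(vapply(seq_len(nrow(Tr)), function(j)
        sqrt(sum((Nw[i, ] - Tr[j, ])^2)), numeric(1))) / dbar
    }, numeric(1))
  }
}

toy_train <- function(n = 30, seed = 5) {
  set.seed(seed)
  data.frame(
    clay_pct = runif(n, 5, 60), silt_pct = runif(n, 10, 50),
    coarse_frac = runif(n, 0, 0.3), slope_deg = runif(n, 0, 8),
    elevation_m = runif(n, 20, 800), drought_index = runif(n, 25, 60),
    map_mm = runif(n, 500, 1500), mat_c = runif(n, 5, 11),
    wrb_group = sample(c("Cambisol", "Gleysol"), n, replace = TRUE),
    parent_material = sample(c("loess", "till"), n, replace = TRUE),
    groundwater_class = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

toy_importance <- function(spec, seed = 6) {
  set.seed(seed)
  setNames(runif(length(c(spec$numeric, spec$categorical))),
           c(spec$numeric, spec$categorical))
}
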