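#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter arrange select left_join inner_join
#'   group_by summarise ungroup bind_rows n row_number desc across all_of
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap keep
#' @importFrom stats pt pnorm phyper dhyper qnorm p.adjust setNames
#'   wilcox.test cor hclust cutree as.dist rnorm runif plogis qlogis
#' @importFrom utils head tail
NULL

# stable 32-bit string hash (polynomial rolling hash, exact in doubles)
hash32 <- function(...) {
  s <- paste(c(...), collapse = "\r")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# run expr with a private RNG stream, restoring the caller's stream after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ceiling subset size used for extreme-quantile sample selection
extreme_count <- function(n_samples, fraction) {
  as.integer(ceiling(fraction * n_samples))
}

ml_log <- function(fmt, ..., verbose = TRUE) {
  if (isTRUE(verbose)) inform(sprintf(fmt, ...))
  invisible(NULL)
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)
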