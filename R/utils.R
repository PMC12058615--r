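#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of (parameters, seed).
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483647)
}

#' Greedy bipartite nearest matching of two point sets
#'
#' Matches detected positions to ground-truth positions by ascending pair
#' distance, each point used at most once, ignoring pairs farther apart than
#' `max_dist`. Used to score detection recovery against generator truth.
#'
#' @param detected,truth two-column matrices or data frames of (x, y) in nm.
#' @param max_dist maximum matching distance in nm.
#' @return list with `matches` (data.frame detected, truth, dist),
#'   `match_rate` (matched / truth count) and `mean_dist`.
#' @export
match_positions <- function(detected, truth, max_dist = 20) {
  D <- as.matrix(detected)[, 1:2, drop = FALSE]
  Tr <- as.matrix(truth)[, 1:2, drop = FALSE]
  if (!nrow(D) || !nrow(Tr))
    return(list(matches = data.frame(detected = integer(0), truth = integer(0),
                                     dist = numeric(0)),
                match_rate = 0, mean_dist = NA_real_))
  dmat <- sqrt(outer(D[, 1], Tr[, 1], "-")^2 + outer(D[, 2], Tr[, 2], "-")^2)
  cand <- which(dmat <= max_dist, arr.ind = TRUE)
  if (!nrow(cand))
    return(list(matches = data.frame(detected = integer(0), truth = integer(0),
                                     dist = numeric(0)),
                match_rate = 0, mean_dist = NA_real_))
  ord <- order(dmat[cand])
  cand <- cand[ord, , drop = FALSE]
  used_d <- logical(nrow(D)); used_t <- logical(nrow(Tr))
  md <- mt <- integer(0); dd <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    md <- c(md, i); mt <- c(mt, j); dd <- c(dd, dmat[i, j])
  }
  list(matches = data.frame(detected = md, truth = mt, dist = dd),
       match_rate = length(md) / nrow(Tr),
       mean_dist = mean(dd))
}
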