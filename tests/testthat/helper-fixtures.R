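# Shared fixtures and independent oracles. Heavyweight objects are built
# once per test run and memoized here.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  v <- .fixture_env[[name]]
  if (is.null(v)) {
    v <- builder()
    .fixture_env[[name]] <- v
  }
  v
}

# one small clean paired recording (60 s) for unit tests
small_clean_pair <- function() {
  fixture("small_clean_pair", function() {
    simulate_paired(cardiac_params(mean_rr = 0.8, rr_sd = 0.03,
                                   rsa_amplitude = 0.02, duration = 60,
                                   seed = 101L))
  })
}

# brute-force peak matcher: enumerates every one-to-one assignment of
# predictions to truths within tolerance, keeps one maximizing the number
# of matched pairs (ties broken preferring earlier matched truths, then
# earlier matched predictions), then applies the same epoch accounting as
# match_peaks. Only feasible for small inputs.
oracle_match <- function(pred, truth, tolerance = 0.1, epoch_len = 1,
                         span) {
  if (length(span) == 1) span <- c(0, span)
  p <- pred[pred >= span[1] & pred < span[2]]
  tt <- truth[truth >= span[1] & truth < span[2]]
  n_epochs <- as.integer(ceiling((span[2] - span[1]) / epoch_len - 1e-9))

  best <- list(n = -1L, tm = rep(FALSE, length(tt)),
               pm = rep(FALSE, length(p)))
  lex_better <- function(a, b) {
    d <- which(a != b)
    length(d) > 0 && a[d[1]]                     # TRUE preferred earlier
  }
  consider <- function(pairs) {
    n <- nrow(pairs)
    tm <- rep(FALSE, length(tt)); tm[pairs$tj] <- TRUE
    pm <- rep(FALSE, length(p)); pm[pairs$pi] <- TRUE
    if (n > best$n ||
        (n == best$n && lex_better(tm, best$tm)) ||
        (n == best$n && identical(tm, best$tm) && lex_better(pm, best$pm))) {
      best <<- list(n = n, tm = tm, pm = pm)
    }
  }
  feasible <- function(i, j) abs(p[i] - tt[j]) <= tolerance
  recurse <- function(j, used_p, pairs) {
    if (j > length(tt)) {
      consider(pairs)
      return(invisible())
    }
    recurse(j + 1, used_p, pairs)                 # leave truth j unmatched
    for (i in seq_along(p)) {
      if (!used_p[i] && feasible(i, j)) {
        up <- used_p; up[i] <- TRUE
        recurse(j + 1, up, rbind(pairs, data.frame(pi = i, tj = j)))
      }
    }
  }
  recurse(1, rep(FALSE, length(p)), data.frame(pi = integer(0),
                                               tj = integer(0)))
  ep_of <- function(x) pmin(floor((x - span[1]) / epoch_len), n_epochs - 1L)
  t_ep <- ep_of(tt); p_ep <- ep_of(p)
  tp <- tn <- fp <- fn <- 0L
  for (e in seq_len(n_epochs) - 1L) {
    ti <- which(t_ep == e)
    if (length(ti) > 0) {
      if (all(best$tm[ti])) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (any(p_ep == e & !best$pm)) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}
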