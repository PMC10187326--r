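#' Two-state HMM smoother parameters
#'
#' Hidden states are the true walk / non-walk labels; emissions are the
#' classifier's predicted labels. Rows and columns are ordered
#' `("walk", "nonwalk")`. Every row is stochastic and, after pseudo-count
#' smoothing, strictly positive.
#'
#' @param prior length-2 probability vector over the initial true state.
#' @param transition 2 x 2 row-stochastic matrix of true-label bigrams.
#' @param emission 2 x 2 row-stochastic matrix; row = true state, column =
#'   predicted label.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(prior, transition, emission) {
  states <- c("walk", "nonwalk")
  prior <- as.numeric(prior); names(prior) <- states
  transition <- matrix(as.numeric(transition), 2, 2,
                       dimnames = list(states, states))
  emission <- matrix(as.numeric(emission), 2, 2,
                     dimnames = list(states, states))
  for (m in list(rbind(prior), transition, emission)) {
    if (any(m < 0) || any(m > 1) || any(abs(rowSums(m) - 1) > 1e-9))
      stopf("HMM probability rows must be in [0,1] and sum to 1")
  }
  structure(list(prior = prior, transition = transition, emission = emission),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> two-state label smoother\n")
  cat(sprintf("  prior:      walk %.3f / nonwalk %.3f\n", x$prior[1], x$prior[2]))
  cat(sprintf("  P(stay walk) %.3f, P(stay nonwalk) %.3f\n",
              x$transition[1, 1], x$transition[2, 2]))
  cat(sprintf("  P(correct | walk) %.3f, P(correct | nonwalk) %.3f\n",
              x$emission[1, 1], x$emission[2, 2]))
  invisible(x)
}

to_state <- function(labels) {
  s <- match(labels, c("walk", "nonwalk"))
  if (anyNA(s)) stopf("labels must be 'walk' or 'nonwalk'")
  s
}

#' Fit the HMM smoother from validation predictions
#'
#' Supervised count-based fit: the emission matrix is the row-normalized
#' confusion matrix of true against predicted labels, the transition matrix
#' the row-normalized bigram counts of the true label sequence, and the prior
#' the smoothed true-label frequencies. A pseudo-count keeps every
#' probability strictly positive even when a fold never exhibits some
#' transition.
#'
#' @param val_predicted predicted labels: a character vector or a list of
#'   per-recording vectors (bigrams are never counted across recordings).
#' @param val_true ground-truth labels, aligned with `val_predicted`.
#' @param pseudo_count additive smoothing count (default 1).
#' @return an [hmm_params] object.
#' @export
fit_hmm <- function(val_predicted, val_true, pseudo_count = 1) {
  if (!is.list(val_predicted)) val_predicted <- list(val_predicted)
  if (!is.list(val_true)) val_true <- list(val_true)
  if (length(val_predicted) != length(val_true))
    stopf("predicted and true label sequences must be aligned")
  emis <- matrix(pseudo_count, 2, 2)
  trans <- matrix(pseudo_count, 2, 2)
  prior <- rep(pseudo_count, 2)
  for (i in seq_along(val_true)) {
    p <- val_predicted[[i]]; tr <- val_true[[i]]
    if (length(p) != length(tr)) stopf("sequence %d: length mismatch", i)
    keep <- !is.na(p) & !is.na(tr) & p != "unknown" & tr != "unknown"
    p <- to_state(p[keep]); tr <- to_state(tr[keep])
    for (j in seq_along(p)) emis[tr[j], p[j]] <- emis[tr[j], p[j]] + 1
    if (length(tr) > 1)
      for (j in seq_len(length(tr) - 1L))
        trans[tr[j], tr[j + 1L]] <- trans[tr[j], tr[j + 1L]] + 1
    for (s in tr) prior[s] <- prior[s] + 1
  }
  norm_rows <- function(m) {
    rs <- rowSums(m)
    if (any(rs == 0)) stopf("degenerate HMM counts; use pseudo_count > 0")
    m / rs
  }
  hmm_params(prior / sum(prior), norm_rows(trans), norm_rows(emis))
}

#' Viterbi smoothing of a predicted label sequence
#'
#' Maximum a-posteriori hidden state path given the predicted labels as
#' emissions. Ties are broken toward the non-walking state (conservative
#' step counting). Sequences are smoothed one recording at a time.
#' Positions labelled `"unknown"` (invalid epochs) are treated as
#' uninformative emissions and returned as `"unknown"`.
#'
#' @param params an [hmm_params].
#' @param predicted character vector of predicted labels.
#' @return character vector of smoothed labels, same length as input.
#' @export
viterbi_smooth <- function(params, predicted) {
  n <- length(predicted)
  if (n == 0L) stopf("cannot smooth an empty label sequence")
  known <- !is.na(predicted) & predicted != "unknown"
  obs <- rep(NA_integer_, n)
  obs[known] <- to_state(predicted[known])
  lp <- log(params$prior)
  lt <- log(params$transition)
  le <- log(params$emission)
  emis_lp <- function(t, s) if (is.na(obs[t])) 0 else le[s, obs[t]]
  delta <- matrix(-Inf, n, 2)
  back <- matrix(1L, n, 2)
  for (s in 1:2) delta[1, s] <- lp[s] + emis_lp(1L, s)
  if (n > 1) for (t in 2:n) for (s in 1:2) {
    cand <- delta[t - 1, ] + lt[, s]
    # tie -> nonwalk predecessor (state index 2)
    best <- if (cand[2] >= cand[1]) 2L else 1L
    delta[t, s] <- cand[best] + emis_lp(t, s)
    back[t, s] <- best
  }
  path <- integer(n)
  path[n] <- if (delta[n, 2] >= delta[n, 1]) 2L else 1L
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  out <- c("walk", "nonwalk")[path]
  out[!known] <- "unknown"
  out
}

# Log-probability of a given state path under the HMM with the observed
# emission sequence; used by tests and sanity assertions.
path_log_prob <- function(params, path_labels, predicted) {
  s <- to_state(path_labels)
  known <- !is.na(predicted) & predicted != "unknown"
  o <- rep(NA_integer_, length(predicted))
  o[known] <- to_state(predicted[known])
  lp <- unname(log(params$prior)[s[1]])
  if (!is.na(o[1])) lp <- lp + log(params$emission)[s[1], o[1]]
  for (t in seq_along(s)[-1]) {
    lp <- lp + log(params$transition)[s[t - 1], s[t]]
    if (!is.na(o[t])) lp <- lp + log(params$emission)[s[t], o[t]]
  }
  lp
}
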