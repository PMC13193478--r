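#' Define one time-stratified SSE model
#'
#' A model in the epoch-structured family: the tree's history is divided at
#' `slice_age` into an early epoch (ages > `slice_age`) and a late epoch.
#' Within each epoch speciation is either *dependent* on the observed binary
#' trait (rates vary by observed state) or *independent* (rates vary only by
#' a hidden state, the character-independent null with matched parameter
#' count).  Observed-state transitions can be symmetric or asymmetric, and
#' transition rates (observed and hidden) either constant through time or
#' free to differ between epochs.
#'
#' Composite states are ordered (obs0,hidA), (obs1,hidA), (obs0,hidB),
#' (obs1,hidB).  Extinction is shared across composite states within an
#' epoch; dual (simultaneous observed+hidden) transitions have rate zero.
#'
#' @param slice_age Epoch boundary (Ma before present).
#' @param early_mode,late_mode `"dependent"` or `"independent"`.
#' @param transition_symmetry `"symmetric"` or `"asymmetric"`.
#' @param transition_time_variation `"constant"` or `"variable"`.
#' @param sliced Logical; `FALSE` gives the unstratified reference model.
#' @param sampling_fraction Length-2 sampling fractions (observed states 0,1).
#' @return An object of class `sse_spec`.
#' @export
sse_model_spec <- function(slice_age, early_mode = "dependent",
                           late_mode = "dependent",
                           transition_symmetry = "asymmetric",
                           transition_time_variation = "constant",
                           sliced = TRUE,
                           sampling_fraction = c(0.6, 0.6)) {
  early_mode <- match.arg(early_mode, c("dependent", "independent"))
  late_mode <- match.arg(late_mode, c("dependent", "independent"))
  transition_symmetry <- match.arg(transition_symmetry,
                                   c("symmetric", "asymmetric"))
  transition_time_variation <- match.arg(transition_time_variation,
                                         c("constant", "variable"))
  stopifnot(slice_age > 0, all(sampling_fraction > 0),
            all(sampling_fraction <= 1))
  spec <- structure(list(slice_age = slice_age, early_mode = early_mode,
                         late_mode = late_mode,
                         transition_symmetry = transition_symmetry,
                         transition_time_variation = transition_time_variation,
                         sliced = sliced,
                         sampling_fraction = sampling_fraction),
                    class = "sse_spec")
  spec$par_names <- sse_par_names(spec)
  spec$k <- length(spec$par_names)
  spec$name <- sse_spec_name(spec)
  spec
}

sse_spec_name <- function(spec) {
  if (!spec$sliced)
    return(paste0("unsliced_",
                  substr(spec$early_mode, 1, 3), "_",
                  substr(spec$transition_symmetry, 1, 4)))
  paste0(substr(spec$early_mode, 1, 3), "-early+",
         substr(spec$late_mode, 1, 3), "-late_",
         substr(spec$transition_symmetry, 1, 4), "_",
         ifelse(spec$transition_time_variation == "variable", "tvar",
                "tconst"))
}

sse_par_names <- function(spec) {
  sym <- spec$transition_symmetry == "symmetric"
  tvar <- spec$transition_time_variation == "variable"
  if (!spec$sliced) {
    return(c("lambda_1", "lambda_2", "mu",
             if (sym) "q_obs" else c("q01", "q10"),
             "q_hidden"))
  }
  c("lambda_early_1", "lambda_early_2", "lambda_late_1", "lambda_late_2",
    "mu_early", "mu_late",
    if (tvar) {
      if (sym) c("q_obs_early", "q_obs_late")
      else c("q01_early", "q10_early", "q01_late", "q10_late")
    } else {
      if (sym) "q_obs" else c("q01", "q10")
    },
    if (tvar) c("q_hidden_early", "q_hidden_late") else "q_hidden")
}

#' Expand free SSE parameters to full per-epoch rate arrays
#'
#' @param spec An `sse_spec`.
#' @param par Named vector of free rates (natural scale) matching
#'   `spec$par_names`.
#' @return List with `lambda` (2x4, rows early/late), `mu` (2x4), `qflat`
#'   (length 32, epoch-major row-major 4x4 generators without diagonals).
#' @export
sse_expand_params <- function(spec, par) {
  if (is.null(names(par)) || !all(spec$par_names %in% names(par)))
    stop("`par` must be named with: ", paste(spec$par_names, collapse = ", "))
  if (any(par < 0)) stop("rates must be non-negative")
  p <- as.list(par[spec$par_names])
  sym <- spec$transition_symmetry == "symmetric"
  tvar <- spec$transition_time_variation == "variable"
  lam_epoch <- function(mode, l1, l2) {
    if (mode == "dependent") c(l1, l2, l1, l2) else c(l1, l1, l2, l2)
  }
  if (!spec$sliced) {
    lam <- lam_epoch(spec$early_mode, p$lambda_1, p$lambda_2)
    lambda <- rbind(lam, lam)
    mu <- rbind(rep(p$mu, 4), rep(p$mu, 4))
    q01 <- rep(if (sym) p$q_obs else p$q01, 2)
    q10 <- rep(if (sym) p$q_obs else p$q10, 2)
    qh <- rep(p$q_hidden, 2)
  } else {
    lambda <- rbind(lam_epoch(spec$early_mode, p$lambda_early_1,
                              p$lambda_early_2),
                    lam_epoch(spec$late_mode, p$lambda_late_1,
                              p$lambda_late_2))
    mu <- rbind(rep(p$mu_early, 4), rep(p$mu_late, 4))
    if (tvar) {
      q01 <- if (sym) c(p$q_obs_early, p$q_obs_late)
             else c(p$q01_early, p$q01_late)
      q10 <- if (sym) c(p$q_obs_early, p$q_obs_late)
             else c(p$q10_early, p$q10_late)
      qh <- c(p$q_hidden_early, p$q_hidden_late)
    } else {
      q01 <- rep(if (sym) p$q_obs else p$q01, 2)
      q10 <- rep(if (sym) p$q_obs else p$q10, 2)
      qh <- rep(p$q_hidden, 2)
    }
  }
  qflat <- numeric(32)
  for (e in 1:2) {
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- q01[e]; Q[3, 4] <- q01[e]   # obs 0 -> 1
    Q[2, 1] <- q10[e]; Q[4, 3] <- q10[e]   # obs 1 -> 0
    Q[1, 3] <- qh[e]; Q[3, 1] <- qh[e]     # hidden A <-> B
    Q[2, 4] <- qh[e]; Q[4, 2] <- qh[e]
    qflat[(e - 1) * 16 + seq_len(16)] <- as.vector(t(Q))
  }
  list(lambda = unname(lambda), mu = unname(mu), qflat = qflat)
}

#' Build the full epoch-scenario model set
#'
#' The crossing of early/late speciation mode (trait-dependent vs
#' hidden-state independent), symmetric vs asymmetric observed transitions,
#' and constant vs time-variable transition rates (16 sliced models), plus
#' the two unstratified references (dependent and independent, asymmetric
#' transitions).
#'
#' @inheritParams sse_model_spec
#' @return List of `sse_spec` objects, each carrying its free-parameter
#'   count `k`.
#' @export
build_model_set <- function(slice_age, sampling_fraction = c(0.6, 0.6)) {
  stopifnot(slice_age > 0)
  specs <- list()
  for (em in c("dependent", "independent"))
    for (lm in c("dependent", "independent"))
      for (sym in c("symmetric", "asymmetric"))
        for (tv in c("constant", "variable"))
          specs[[length(specs) + 1]] <-
            sse_model_spec(slice_age, em, lm, sym, tv, sliced = TRUE,
                           sampling_fraction = sampling_fraction)
  for (m in c("dependent", "independent"))
    specs[[length(specs) + 1]] <-
      sse_model_spec(slice_age, m, m, "asymmetric", "constant",
                     sliced = FALSE, sampling_fraction = sampling_fraction)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
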