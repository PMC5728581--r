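# Small labelled-state Markov models of nucleosome repositioning routes:
# detailed-balance rate completion, exact mean first passage times and a
# Gillespie stochastic-simulation oracle. Times are expressed in MD steps
# throughout, matching how coarse-grained simulation rates are reported;
# no mapping to physical seconds is attempted.

#' Construct a labelled-state rate model
#'
#' @param states character vector of state labels.
#' @param rates data.frame with columns \code{from, to, rate} (rate in
#'   1/MD-steps); self-rates are forbidden.
#' @return a \code{rate_model}.
#' @export
rate_model <- function(states, rates) {
  states <- as.character(states)
  stopifnot(is.data.frame(rates),
            all(c("from", "to", "rate") %in% names(rates)))
  if (any(!rates$from %in% states) || any(!rates$to %in% states))
    stop("rates refer to unknown states")
  if (any(rates$from == rates$to)) stop("self-rates are not allowed")
  if (any(rates$rate < 0)) stop("rates must be non-negative")
  structure(list(states = states, rates = rates), class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("rate_model:", length(x$states), "states,",
      nrow(x$rates), "transitions\n")
  for (i in seq_len(nrow(x$rates)))
    cat(sprintf("  %s -> %s : %.4g /step (1/rate = %.4g steps)\n",
                x$rates$from[i], x$rates$to[i], x$rates$rate[i],
                1 / x$rates$rate[i]))
  invisible(x)
}

# dense rate matrix Q[i,j] = rate i->j
.rate_matrix <- function(model) {
  n <- length(model$states)
  Q <- matrix(0, n, n, dimnames = list(model$states, model$states))
  for (i in seq_len(nrow(model$rates)))
    Q[model$rates$from[i], model$rates$to[i]] <- Q[model$rates$from[i],
                                                   model$rates$to[i]] +
      model$rates$rate[i]
  Q
}

#' Forward rate from detailed balance
#'
#' Completes a rate pair across a free-energy difference:
#' \eqn{k_{fwd} = k_{rev}\, e^{-\Delta F}} with \code{delta_F} the free
#' energy of the destination (e.g. a loop-defect intermediate) relative to
#' the origin, in kBT.
#'
#' @param k_reverse reverse rate, 1/MD-steps.
#' @param delta_F free-energy difference, kBT.
#' @return forward rate, 1/MD-steps.
#' @examples
#' # forming a ~15 kBT loop defect that dissipates once per 8e4 steps:
#' detailed_balance_rate(1 / 8e4, 15)
#' @export
detailed_balance_rate <- function(k_reverse, delta_F) {
  stopifnot(k_reverse > 0, is.finite(delta_F))
  k_reverse * exp(-delta_F)
}

#' Mean first passage time by linear solve
#'
#' Exact MFPT from the first-step equations: for each non-target state i,
#' \eqn{(\sum_j k_{ij}) T_i - \sum_{j \notin targets} k_{ij} T_j = 1}.
#'
#' @param model a \code{rate_model}.
#' @param start starting state label.
#' @param targets target state label(s).
#' @return MFPT in MD steps.
#' @export
mfpt <- function(model, start, targets) {
  stopifnot(start %in% model$states, all(targets %in% model$states))
  if (start %in% targets) return(0)
  Q <- .rate_matrix(model)
  free <- setdiff(model$states, targets)
  # reachability of targets from start along positive rates
  reach <- start
  repeat {
    nxt <- unique(model$rates$to[model$rates$from %in% reach &
                                   model$rates$rate > 0])
    new <- setdiff(nxt, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  if (!any(targets %in% reach))
    stop("target unreachable from start; MFPT is infinite")
  A <- -Q[free, free, drop = FALSE]
  diag(A) <- diag(A) + rowSums(Q[free, , drop = FALSE])
  T <- solve(A, rep(1, length(free)))
  unname(T[match(start, free)])
}

#' First-passage times by Gillespie stochastic simulation
#'
#' Kinetic Monte-Carlo oracle for \code{\link{mfpt}}: simulates
#' \code{n_replicates} continuous-time trajectories from \code{start}
#' until a target (or the event cap) is reached.
#'
#' @param model a \code{rate_model}.
#' @param start starting state label.
#' @param targets target state label(s).
#' @param n_replicates number of independent replicates.
#' @param seed RNG seed.
#' @param max_events per-replicate event cap guarding against unreachable
#'   targets.
#' @return list with \code{mean}, \code{sem}, \code{times} (MD steps) and
#'   \code{n_capped}.
#' @export
gillespie <- function(model, start, targets, n_replicates = 1000, seed = 1,
                      max_events = 1e6) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  Q <- .rate_matrix(model)
  n <- length(model$states)
  exit <- rowSums(Q)
  probs <- Q / ifelse(exit > 0, exit, 1)
  target_idx <- match(targets, model$states)
  state <- rep(match(start, model$states), n_replicates)
  t_acc <- numeric(n_replicates)
  active <- !(state %in% target_idx)
  capped <- logical(n_replicates)
  ev <- 0
  while (any(active) && ev < max_events) {
    ev <- ev + 1
    idx <- which(active)
    s <- state[idx]
    lam <- exit[s]
    if (any(lam == 0)) stop("active state with no outgoing rate")
    t_acc[idx] <- t_acc[idx] + stats::rexp(length(idx), lam)
    u <- stats::runif(length(idx))
    cp <- t(apply(probs[s, , drop = FALSE], 1, cumsum))
    nxt <- max.col(u < cp, ties.method = "first")
    state[idx] <- nxt
    active[idx] <- !(nxt %in% target_idx)
  }
  if (any(active)) {
    capped[active] <- TRUE
    warning(sum(active), " replicate(s) hit the event cap")
  }
  times <- t_acc[!capped]
  list(mean = mean(times),
       sem = stats::sd(times) / sqrt(length(times)),
       times = times, n_capped = sum(capped))
}

#' Shipped 3-state repositioning route models
#'
#' The three candidate routes from the initial (crystal-like) nucleosome
#' position to the 10-bp-shifted position, each through one intermediate:
#' \describe{
#'   \item{uncoupled}{rotation-uncoupled route via the 5-bp-shifted state
#'     (most hydrogen bonds broken in the intermediate).}
#'   \item{coupled}{rotation-coupled (screw-like) route via a 5-bp-rotated
#'     intermediate.}
#'   \item{loop}{DNA reptation via a loop defect stored at one end; the
#'     formation rate is completed from detailed balance against the loop
#'     free-energy cost.}
#' }
#' The loop route defaults reproduce measured loop kinetics: dissipation
#' once per 8e4 MD steps, diffusion to the far end once per 7e6 MD steps,
#' and a loop cost of 15 kBT.
#'
#' @param route one of \code{"loop"}, \code{"uncoupled"}, \code{"coupled"}.
#' @param k_intermediate_exit_back rate intermediate -> start, 1/steps.
#' @param k_intermediate_exit_fwd rate intermediate -> shifted, 1/steps.
#' @param k_enter rate start -> intermediate; if \code{NULL} and
#'   \code{delta_F} is given, completed by detailed balance from the
#'   backward exit rate.
#' @param delta_F intermediate free energy relative to the start, kBT.
#' @param symmetric also add the mirrored shifted -> intermediate -> start
#'   rates (default TRUE).
#' @return a \code{rate_model} with states \code{crystal},
#'   \code{intermediate}, \code{shifted10}.
#' @export
route_model <- function(route = c("loop", "uncoupled", "coupled"),
                        k_intermediate_exit_back = 1 / 8e4,
                        k_intermediate_exit_fwd = 1 / 7e6,
                        k_enter = NULL, delta_F = 15, symmetric = TRUE) {
  route <- match.arg(route)
  if (is.null(k_enter)) {
    if (is.null(delta_F))
      stop("either k_enter or delta_F must be given")
    k_enter <- detailed_balance_rate(k_intermediate_exit_back, delta_F)
  }
  rates <- data.frame(
    from = c("crystal", "intermediate", "intermediate"),
    to = c("intermediate", "crystal", "shifted10"),
    rate = c(k_enter, k_intermediate_exit_back, k_intermediate_exit_fwd))
  if (symmetric) {
    rates <- rbind(rates, data.frame(
      from = c("shifted10", "intermediate"),
      to = c("intermediate", "shifted10"),
      rate = c(k_enter, 0))[1, , drop = FALSE])
  }
  m <- rate_model(c("crystal", "intermediate", "shifted10"), rates)
  attr(m, "route") <- route
  m
}
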