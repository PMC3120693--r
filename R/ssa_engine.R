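#' Run a delayed stochastic simulation
#'
#' Simulates a [reaction_system()] from t = 0 to `t_stop` with the delayed
#' stochastic simulation algorithm. The algorithm keeps a waiting list of
#' delayed product releases ordered by release time (FIFO among ties). At
#' each step a candidate reaction and waiting time are drawn by a standard
#' SSA step; if the candidate would occur strictly before the earliest
#' pending release it fires (queueing its delayed products), otherwise the
#' head of the waiting list is released and the candidate discarded. When
#' the total propensity is zero but releases are pending, time jumps to the
#' next release; when both are exhausted, time advances to `t_stop`.
#'
#' Two engines are provided: `"cpp"` (the default, compiled) and `"r"`, a
#' pure-R reference implementation built on [advance_one_event()]. Both
#' draw their randomness from R's RNG, so a seed makes a run reproducible,
#' but the two engines consume the stream differently and are compared in
#' distribution, not per-event.
#'
#' @param system a [reaction_system()].
#' @param t_stop simulation end time in seconds (>= 0).
#' @param seed optional integer seed applied with [set.seed()] before
#'   simulating; `NULL` continues the current RNG stream.
#' @param sampling optional sampling interval in seconds; when given, the
#'   result carries a time series of counts at `seq(0, t_stop, by = sampling)`.
#' @param engine `"cpp"` or `"r"`.
#' @return an object of class `sim_result`: a list with `t_stop`,
#'   `final_counts` and `pending_counts` (named integer vectors), `series`
#'   (a data.frame of time plus one column per species, or `NULL`) and
#'   `n_events`, the number of executed reaction firings plus releases.
#' @examples
#' sys <- reaction_system(
#'   list(reaction(1, NULL, list(product("X", delay = delay_constant(5))))),
#'   c(X = 0))
#' run_simulation(sys, t_stop = 10, seed = 1)$final_counts
#' @export
run_simulation <- function(system, t_stop, seed = NULL, sampling = NULL,
                           engine = c("cpp", "r")) {
  stopifnot(inherits(system, "reaction_system"))
  engine <- match.arg(engine)
  if (!is.numeric(t_stop) || length(t_stop) != 1L || is.na(t_stop) || t_stop < 0)
    stop("t_stop must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  sample_times <- if (is.null(sampling)) numeric(0) else {
    if (!is.numeric(sampling) || sampling <= 0)
      stop("sampling must be a positive interval in seconds")
    seq(0, t_stop, by = sampling)
  }

  if (engine == "cpp") {
    res <- .ssa_run_cpp(length(system$species), encode_reactions(system),
                        unname(system$initial_counts), t_stop, sample_times)
    final <- stats::setNames(res$final_counts, system$species)
    pending <- stats::setNames(res$pending_counts, system$species)
    series <- if (length(sample_times)) {
      df <- as.data.frame(res$series)
      names(df) <- system$species
      cbind(data.frame(time = sample_times), df)
    } else NULL
    out <- list(t_stop = t_stop, final_counts = final,
                pending_counts = pending, series = series,
                n_events = as.integer(res$n_events))
  } else {
    out <- ssa_run_r(system, t_stop, sample_times)
  }
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: t_stop = %g s, %d events\n", x$t_stop, x$n_events))
  cat("  final counts: ",
      paste(names(x$final_counts), x$final_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# reactions in the index form the C++ engine consumes (0-based species)
encode_reactions <- function(system) {
  idx <- stats::setNames(seq_along(system$species) - 1L, system$species)
  lapply(system$reactions, function(r) {
    rm <- if (length(r$reactants))
      cbind(species = unname(idx[names(r$reactants)]),
            stoich = unname(r$reactants))
    else matrix(integer(0), 0, 2,
                dimnames = list(NULL, c("species", "stoich")))
    np <- length(r$products)
    pm <- data.frame(
      species = if (np) vapply(r$products, function(p) idx[[p$species]], integer(1)) else integer(0),
      stoich = if (np) vapply(r$products, function(p) p$stoich, integer(1)) else integer(0),
      kind = if (np) vapply(r$products, function(p)
        match(p$delay$kind, c("zero", "constant", "gamma")) - 1L, integer(1)) else integer(0),
      mean = if (np) vapply(r$products, function(p) p$delay$mean, numeric(1)) else numeric(0),
      sd = if (np) vapply(r$products, function(p) p$delay$sd, numeric(1)) else numeric(0))
    list(rate = r$rate, reactants = rm, products = pm)
  })
}

#' Initialise the state of a stepwise simulation
#'
#' @param system a [reaction_system()].
#' @return a `sim_state` list with current time `t`, named `counts`, the
#'   waiting list (a data.frame with columns `time`, `seq`, `species`,
#'   `count`), the event counter and a `status` of `"running"` or `"done"`.
#' @export
sim_state <- function(system) {
  structure(list(t = 0, counts = system$initial_counts,
                 waitlist = data.frame(time = numeric(0), seq = integer(0),
                                       species = character(0),
                                       count = integer(0),
                                       stringsAsFactors = FALSE),
                 next_seq = 1L, n_events = 0L, status = "running"),
            class = "sim_state")
}

propensities <- function(system, counts) {
  vapply(system$reactions, function(r) {
    a <- r$rate
    for (j in seq_along(r$reactants)) {
      n <- counts[[names(r$reactants)[j]]]
      a <- a * if (r$reactants[j] == 1L) n else n * (n - 1) / 2
    }
    a
  }, numeric(1))
}

waitlist_head <- function(wl) {
  if (!nrow(wl)) return(NULL)
  ord <- order(wl$time, wl$seq)
  ord[1]
}

#' Advance the delayed SSA by one event
#'
#' Executes one iteration of the algorithm's inner loop on an explicit
#' state: draw a candidate (reaction, waiting time); fire it if it precedes
#' the earliest pending release, otherwise release the waiting-list head
#' (ties release first). With zero total propensity and an empty waiting
#' list, time advances to `t_stop` and the state is marked done. This is
#' the reference implementation; [run_simulation()] with `engine = "cpp"`
#' is the fast path.
#'
#' @param state a `sim_state` from [sim_state()].
#' @param system the [reaction_system()] being simulated.
#' @param t_stop end time; events that would land past it are not executed.
#' @return the updated `sim_state`.
#' @export
advance_one_event <- function(state, system, t_stop) {
  stopifnot(inherits(state, "sim_state"))
  if (state$status == "done") return(state)
  a <- propensities(system, state$counts)
  a0 <- sum(a)
  hd <- waitlist_head(state$waitlist)
  t_min <- if (is.null(hd)) Inf else state$waitlist$time[hd]

  fire <- FALSE
  if (a0 <= 0) {
    t_next <- if (is.null(hd)) t_stop else t_min
  } else {
    t1 <- stats::rexp(1, rate = a0)
    if (state$t + t1 < t_min) {
      t_next <- state$t + t1
      fire <- TRUE
      which_r <- sample.int(length(a), 1L, prob = a)
    } else t_next <- t_min
  }

  if (t_next >= t_stop) {
    state$t <- t_stop
    state$status <- "done"
    return(state)
  }
  state$t <- t_next

  if (fire) {
    r <- system$reactions[[which_r]]
    for (j in seq_along(r$reactants)) {
      sp <- names(r$reactants)[j]
      state$counts[[sp]] <- state$counts[[sp]] - r$reactants[[j]]
      if (state$counts[[sp]] < 0)
        stop("negative molecule count: invariant violated")
    }
    for (p in r$products) {
      if (p$delay$kind == "zero") {
        state$counts[[p$species]] <- state$counts[[p$species]] + p$stoich
      } else {
        for (m in seq_len(p$stoich)) {
          state$waitlist <- rbind(state$waitlist, data.frame(
            time = state$t + sample_delay(p$delay, 1L),
            seq = state$next_seq, species = p$species, count = 1L,
            stringsAsFactors = FALSE))
          state$next_seq <- state$next_seq + 1L
        }
      }
    }
  } else {
    state$counts[[state$waitlist$species[hd]]] <-
      state$counts[[state$waitlist$species[hd]]] + state$waitlist$count[hd]
    state$waitlist <- state$waitlist[-hd, , drop = FALSE]
  }
  state$n_events <- state$n_events + 1L
  state
}

ssa_run_r <- function(system, t_stop, sample_times) {
  state <- sim_state(system)
  ns <- length(sample_times)
  series <- if (ns) matrix(NA_real_, ns, length(system$species)) else NULL
  si <- 1L
  repeat {
    prev_counts <- state$counts
    prev_t <- state$t
    state <- advance_one_event(state, system, t_stop)
    t_new <- state$t
    while (si <= ns && sample_times[si] < t_new && sample_times[si] >= prev_t) {
      series[si, ] <- unname(prev_counts)
      si <- si + 1L
    }
    if (state$status == "done") break
  }
  while (si <= ns && sample_times[si] <= t_stop) {
    series[si, ] <- unname(state$counts)
    si <- si + 1L
  }
  pending <- stats::setNames(integer(length(system$species)), system$species)
  if (nrow(state$waitlist)) {
    agg <- tapply(state$waitlist$count, state$waitlist$species, sum)
    pending[names(agg)] <- as.integer(agg)
  }
  sdf <- if (ns) {
    df <- as.data.frame(series)
    names(df) <- system$species
    cbind(data.frame(time = sample_times), df)
  } else NULL
  list(t_stop = t_stop, final_counts = unlist(state$counts),
       pending_counts = pending, series = sdf, n_events = state$n_events)
}

#' Write a simulated trajectory as CSV
#'
#' @param result a `sim_result` carrying a sampled time series.
#' @param path output CSV path (columns: time, one per species).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  if (is.null(result$series))
    stop("result has no sampled time series; rerun with sampling =")
  utils::write.csv(result$series, path, row.names = FALSE)
  invisible(path)
}
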