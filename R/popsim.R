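# Forward-time population model of the karyomorph polymorphism.  Generations
# are non-overlapping; every dam mates a male drawn at random from the male
# pool (all viable males are KI under the XY-female mechanisms, so mate
# identity never varies); per-dam offspring output is proportional to a
# per-karyomorph fecundity multiplier times the viable-zygote fraction of
# her cross.  A deterministic mode iterates the expectation map on female
# karyomorph frequencies; a stochastic mode draws counts multinomially.

.FEMALE_KARYOMORPHS <- c("KII", "KIII", "KIV")

#' Population state
#'
#' @param females named vector over \code{KII}, \code{KIII}, \code{KIV}:
#'   counts (stochastic mode) or frequencies summing to 1 (deterministic
#'   mode).
#' @param males number of males (stochastic mode; all males are KI).
#'   Ignored in deterministic mode.
#' @param generation generation index.
#' @param mode \code{"deterministic"} or \code{"stochastic"}.
#' @return An object of class \code{"population_state"}.
#' @examples
#' population_state(c(KII = 1, KIII = 1, KIV = 1) / 3)
#' @export
population_state <- function(females, males = 0, generation = 0L,
                             mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  f <- stats::setNames(rep(0, 3), .FEMALE_KARYOMORPHS)
  if (!all(names(females) %in% .FEMALE_KARYOMORPHS))
    stop("female karyomorphs must be among KII, KIII, KIV", call. = FALSE)
  f[names(females)] <- females
  if (any(f < 0) || males < 0)
    stop("counts/frequencies must be non-negative", call. = FALSE)
  if (mode == "deterministic" && sum(f) > 0) f <- f / sum(f)
  structure(list(females = f, males = males, generation = as.integer(generation),
                 mode = mode, extinct = sum(f) == 0 &&
                   (mode == "deterministic" || males == 0)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population state> generation %d (%s mode)%s\n", x$generation,
              x$mode, if (x$extinct) " EXTINCT" else ""))
  cat("  females:", paste(names(x$females), format(x$females, digits = 4),
                          sep = "=", collapse = ", "), "\n")
  if (x$mode == "stochastic") cat("  males (KI):", x$males, "\n")
  invisible(x)
}

# Per-dam offspring machinery shared by both modes: for each dam karyomorph,
# the unnormalized distribution over (sex, karyomorph) classes of surviving
# offspring, scaled by fecundity x viable-zygote fraction.
dam_offspring_table <- function(hypothesis, params, fecundity) {
  lapply(stats::setNames(nm = .FEMALE_KARYOMORPHS), function(dam) {
    d <- cross(dam, "KI", hypothesis, params)
    viable_mass <- sum(d$raw_p * d$viability)
    v <- d[d$viable, c("karyomorph", "sex", "norm_p")]
    v$weight <- v$norm_p * viable_mass * fecundity[[dam]]
    v
  })
}

#' Advance a population one generation
#'
#' Computes the next generation from the current one.  Deterministic mode
#' applies the expectation map exactly to female karyomorph frequencies;
#' stochastic mode draws, for each dam, an offspring number from a Poisson
#' distribution with mean \code{mean_offspring} scaled by her fecundity and
#' viable-zygote fraction, then offspring classes multinomially from her
#' cross distribution.  Populations exceeding \code{capacity} are randomly
#' thinned.  A population with no dams (or, stochastically, no males) is
#' flagged extinct and returned unchanged.
#'
#' @param state a \code{\link{population_state}}.
#' @inheritParams cross
#' @param fecundity named non-negative multipliers per dam karyomorph
#'   (default all 1); KIV subfertility is expressed here.
#' @param mean_offspring stochastic mode: mean surviving offspring per dam
#'   at fecundity 1 and full viability.
#' @param capacity stochastic mode: maximum population size after thinning.
#' @return The next \code{\link{population_state}}.
#' @examples
#' st <- population_state(c(KII = 1, KIII = 1, KIV = 1) / 3)
#' step_generation(st, "mech_a")
#' @export
step_generation <- function(state, hypothesis = "mech_a",
                            params = cross_params(),
                            fecundity = c(KII = 1, KIII = 1, KIV = 1),
                            mean_offspring = 8.6, capacity = 1000) {
  stopifnot(inherits(state, "population_state"))
  hypothesis <- match_hypothesis(hypothesis)
  fec <- stats::setNames(rep(1, 3), .FEMALE_KARYOMORPHS)
  fec[names(fecundity)] <- fecundity
  if (any(fec < 0)) stop("fecundity must be non-negative", call. = FALSE)
  if (state$extinct) return(state)
  tabs <- dam_offspring_table(hypothesis, params, fec)

  if (state$mode == "deterministic") {
    pool <- stats::setNames(numeric(0), character(0))
    add <- function(pool, keys, w) {
      for (i in seq_along(keys))
        pool[keys[i]] <- (if (keys[i] %in% names(pool)) pool[[keys[i]]] else 0) + w[i]
      pool
    }
    for (dam in .FEMALE_KARYOMORPHS) {
      if (state$females[[dam]] == 0) next
      t <- tabs[[dam]]
      pool <- add(pool, paste(t$sex, t$karyomorph, sep = "."),
                  state$females[[dam]] * t$weight)
    }
    fem <- grepl("^female\\.", names(pool))
    fk <- sub("^female\\.", "", names(pool)[fem])
    f <- stats::setNames(rep(0, 3), .FEMALE_KARYOMORPHS)
    stopifnot(all(fk %in% .FEMALE_KARYOMORPHS))  # males always KI; daughters KII-KIV
    f[fk] <- pool[fem]
    out <- population_state(if (sum(f) > 0) f / sum(f) else f,
                            generation = state$generation + 1L,
                            mode = "deterministic")
    attr(out, "sex_ratio") <- sum(pool[!fem]) / sum(pool)
    return(out)
  }

  # stochastic mode
  if (sum(state$females) == 0 || state$males == 0) {
    state$extinct <- TRUE
    return(state)
  }
  sons <- 0L
  daughters <- stats::setNames(rep(0L, 3), .FEMALE_KARYOMORPHS)
  for (dam in .FEMALE_KARYOMORPHS) {
    n_dams <- state$females[[dam]]
    if (n_dams == 0) next
    t <- tabs[[dam]]
    rel_fec <- sum(t$weight)  # fecundity x viable fraction
    n_off <- stats::rpois(n_dams, mean_offspring * rel_fec)
    total <- sum(n_off)
    if (total == 0) next
    cls <- stats::rmultinom(1, total, t$weight / sum(t$weight))[, 1]
    for (k in seq_along(cls)) {
      if (t$sex[k] == "male") sons <- sons + cls[k]
      else daughters[[t$karyomorph[k]]] <- daughters[[t$karyomorph[k]]] + cls[k]
    }
  }
  total <- sons + sum(daughters)
  if (total > capacity) {
    keep <- sample(rep(c("son", names(daughters)), c(sons, daughters)),
                   capacity)
    sons <- sum(keep == "son")
    daughters <- vapply(.FEMALE_KARYOMORPHS,
                        function(k) sum(keep == k), 0L)
  }
  out <- population_state(daughters, males = sons,
                          generation = state$generation + 1L,
                          mode = "stochastic")
  attr(out, "sex_ratio") <- if (total > 0) sons / (sons + sum(daughters)) else NA
  out
}

#' Run a multi-generation trajectory
#'
#' Iterates \code{\link{step_generation}} and collects the trajectory in long
#' format.  Stochastic runs are fully reproducible from the single integer
#' \code{seed}.
#'
#' @inheritParams step_generation
#' @param initial starting \code{\link{population_state}}.
#' @param n_generations number of generations to simulate (>= 1).
#' @param seed integer seed for stochastic mode (ignored in deterministic
#'   mode).
#' @return A data frame with columns \code{generation}, \code{sex},
#'   \code{karyomorph} and \code{value} (frequency or count), one block per
#'   generation including generation 0; attribute \code{"final"} holds the
#'   last state.
#' @examples
#' st <- population_state(c(KII = 1, KIII = 1, KIV = 1) / 3)
#' tr <- run_trajectory(st, 10)
#' @export
run_trajectory <- function(initial, n_generations, hypothesis = "mech_a",
                           params = cross_params(),
                           fecundity = c(KII = 1, KIII = 1, KIV = 1),
                           mean_offspring = 8.6, capacity = 1000,
                           seed = NULL) {
  stopifnot(n_generations >= 1)
  if (initial$mode == "stochastic" && !is.null(seed)) set.seed(seed)
  states <- vector("list", n_generations + 1L)
  states[[1L]] <- initial
  st <- initial
  for (g in seq_len(n_generations)) {
    st <- step_generation(st, hypothesis, params, fecundity,
                          mean_offspring, capacity)
    states[[g + 1L]] <- st
    if (st$extinct) { states <- states[seq_len(g + 1L)]; break }
  }
  rows <- lapply(states, function(s) {
    d <- data.frame(generation = s$generation,
                    sex = c(rep("female", 3), "male"),
                    karyomorph = c(.FEMALE_KARYOMORPHS, "KI"),
                    value = c(unname(s$females),
                              if (s$mode == "stochastic") s$males else
                                NA_real_),
                    stringsAsFactors = FALSE)
    d
  })
  out <- do.call(rbind, rows)
  structure(out, final = st, mode = initial$mode,
            class = c("popsim_trajectory", "data.frame"))
}

#' Deterministic equilibrium of the karyomorph frequency map
#'
#' Iterates the deterministic expectation map from a starting composition
#' until the female karyomorph frequencies change by less than \code{tol}
#' (sup norm) or \code{max_iter} is reached.  Convergence is reported, never
#' assumed.  Under fully Mendelian defaults (no selection, full KIV
#' viability and fecundity) the KIV frequency grows toward fixation, so
#' maintaining KIV at the low observed frequency requires reduced
#' double-neo-X1 viability and/or KIV fecundity.
#'
#' @inheritParams step_generation
#' @param init starting female frequencies (default equal).
#' @param tol convergence tolerance (> 0) on the frequency change.
#' @param max_iter iteration cap.
#' @return A list with \code{frequencies} (female karyomorph frequencies),
#'   \code{sex_ratio} (male proportion at birth at equilibrium),
#'   \code{iterations} and \code{converged}.
#' @examples
#' deterministic_equilibrium("mech_a", cross_params(v_X1X1 = 0.2))
#' @export
deterministic_equilibrium <- function(hypothesis = "mech_a",
                                      params = cross_params(),
                                      fecundity = c(KII = 1, KIII = 1, KIV = 1),
                                      init = c(KII = 1, KIII = 1, KIV = 1) / 3,
                                      tol = 1e-12, max_iter = 10000L) {
  stopifnot(tol > 0)
  st <- population_state(init, mode = "deterministic")
  converged <- FALSE
  it <- 0L
  sr <- NA_real_
  while (it < max_iter) {
    nxt <- step_generation(st, hypothesis, params, fecundity)
    it <- it + 1L
    sr <- attr(nxt, "sex_ratio")
    if (max(abs(nxt$females - st$females)) < tol) {
      st <- nxt; converged <- TRUE; break
    }
    st <- nxt
  }
  list(frequencies = st$females, sex_ratio = sr, iterations = it,
       converged = converged)
}
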