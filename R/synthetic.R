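# Synthetic breeding-colony generator: emulates the crossbreeding design
# (dams of karyomorphs KII-KIV mated to KI sires, surviving offspring sexed,
# a subsample of daughters karyotyped) so that every analysis stage can be
# exercised, and parameter recovery checked, without any live data.

#' Breeding experiment design
#'
#' Describes a breeding colony to simulate.  Defaults reproduce the scale of
#' the real experiment: 17 KII, 18 KIII and 3 KIV dams; a mean of 8.6
#' surviving offspring per dam (327 offspring / 38 dams) drawn from a
#' negative binomial with dispersion \code{size = 10}; about a third of
#' daughters karyotyped (64 of 196).
#'
#' @param n_dams named vector of dam counts per karyomorph.
#' @param mean_offspring mean surviving offspring per dam.
#' @param dispersion negative-binomial size parameter; \code{Inf} gives
#'   Poisson litter totals.
#' @param karyotyped_fraction fraction of each dam's daughters karyotyped,
#'   in [0, 1].
#' @return An object of class \code{"breeding_design"}.
#' @examples
#' breeding_design()
#' breeding_design(n_dams = c(KII = 100), karyotyped_fraction = 1)
#' @export
breeding_design <- function(n_dams = c(KII = 17, KIII = 18, KIV = 3),
                            mean_offspring = 8.6, dispersion = 10,
                            karyotyped_fraction = 0.33) {
  full <- c(KII = 0L, KIII = 0L, KIV = 0L)
  if (!all(names(n_dams) %in% names(full)))
    stop("dam karyomorphs must be among KII, KIII, KIV", call. = FALSE)
  full[names(n_dams)] <- as.integer(n_dams)
  if (any(full < 0)) stop("dam counts must be non-negative", call. = FALSE)
  if (karyotyped_fraction < 0 || karyotyped_fraction > 1)
    stop("'karyotyped_fraction' must lie in [0, 1]", call. = FALSE)
  if (mean_offspring < 0 || dispersion <= 0)
    stop("'mean_offspring' must be >= 0 and 'dispersion' > 0", call. = FALSE)
  structure(list(n_dams = full, mean_offspring = mean_offspring,
                 dispersion = dispersion,
                 karyotyped_fraction = karyotyped_fraction),
            class = "breeding_design")
}

#' Simulate a breeding experiment
#'
#' For every dam, draws the number of surviving offspring from a negative
#' binomial (Poisson when \code{dispersion = Inf}), then each offspring's
#' (sex, karyomorph) class from the viable offspring distribution of her
#' cross with a KI sire under the given hypothesis and parameters; offspring
#' are independent within and between dams (no litter effects).  Daughters
#' are then karyotyped per \code{\link{simulate_karyotyped_daughters}}.  The
#' whole simulation is reproducible from the single integer \code{seed}.
#'
#' @param design a \code{\link{breeding_design}}.
#' @inheritParams cross
#' @param seed integer seed.
#' @return A list with \code{per_dam} (data frame: dam_id, dam_karyomorph,
#'   sire_karyomorph, n_sons, n_daughters, k_KII, k_KIII, k_KIV) and
#'   \code{counts} (the pooled \code{\link{progeny_counts}}); attributes
#'   record the seed, hypothesis and parameters.
#' @examples
#' sim <- simulate_breeding_experiment(breeding_design(), seed = 1)
#' sim$counts
#' @export
simulate_breeding_experiment <- function(design = breeding_design(),
                                         hypothesis = "mech_a",
                                         params = cross_params(),
                                         seed = 1L) {
  stopifnot(inherits(design, "breeding_design"))
  hypothesis <- match_hypothesis(hypothesis)
  set.seed(as.integer(seed))
  rows <- list()
  dam_no <- 0L
  for (dam in names(design$n_dams)) {
    nd <- design$n_dams[[dam]]
    if (nd == 0L) next
    d <- cross(dam, "KI", hypothesis, params)
    v <- d[d$viable, ]
    for (i in seq_len(nd)) {
      dam_no <- dam_no + 1L
      n_off <- as.integer(if (is.finite(design$dispersion))
        stats::rnbinom(1, mu = design$mean_offspring,
                       size = design$dispersion)
      else stats::rpois(1, design$mean_offspring))
      cls <- if (n_off > 0)
        stats::rmultinom(1, n_off, v$norm_p)[, 1] else rep(0L, nrow(v))
      sons <- as.integer(sum(cls[v$sex == "male"]))
      dk <- vapply(c("KII", "KIII", "KIV"), function(k)
        as.integer(sum(cls[v$sex == "female" & v$karyomorph == k])), 0L)
      rows[[dam_no]] <- data.frame(
        dam_id = sprintf("%s_%02d", dam, i), dam_karyomorph = dam,
        sire_karyomorph = "KI", n_sons = sons,
        n_daughters = n_off - sons,
        d_KII = dk[["KII"]], d_KIII = dk[["KIII"]], d_KIV = dk[["KIV"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    per_dam <- data.frame(dam_id = character(0), dam_karyomorph = character(0),
                          sire_karyomorph = character(0),
                          n_sons = integer(0), n_daughters = integer(0),
                          d_KII = integer(0), d_KIII = integer(0),
                          d_KIV = integer(0), k_KII = integer(0),
                          k_KIII = integer(0), k_KIV = integer(0),
                          stringsAsFactors = FALSE)
    counts <- progeny_counts(data.frame(
      dam_karyomorph = character(0), n_dams = integer(0),
      n_sons = integer(0), n_daughters = integer(0)))
    return(structure(list(per_dam = per_dam, counts = counts),
                     seed = seed, hypothesis = hypothesis, params = params))
  }
  per_dam <- do.call(rbind, rows)
  per_dam <- simulate_karyotyped_daughters(per_dam,
                                           design$karyotyped_fraction)
  counts <- progeny_counts(per_dam)
  structure(list(per_dam = per_dam, counts = counts),
            seed = seed, hypothesis = hypothesis, params = params)
}

#' Karyotype a subsample of daughters
#'
#' Takes a per-dam table holding the true daughter karyomorph counts
#' (columns \code{d_KII}, \code{d_KIII}, \code{d_KIV}) and karyotypes, for
#' each dam, a simple random subsample without replacement of
#' \code{round(fraction * n_daughters)} daughters, filling the observed
#' \code{k_KII}, \code{k_KIII}, \code{k_KIV} columns.  Subsampling is
#' performed on the current RNG stream; call \code{set.seed()} first (or set
#' \code{seed}) for reproducibility.
#'
#' @param per_dam per-dam data frame from
#'   \code{\link{simulate_breeding_experiment}}.
#' @param fraction fraction of daughters karyotyped per dam, in [0, 1].
#' @param seed optional integer seed.
#' @return The per-dam table with \code{k_KII}, \code{k_KIII}, \code{k_KIV}
#'   columns replaced by the karyotyped subsample counts.
#' @export
simulate_karyotyped_daughters <- function(per_dam, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1)
    stop("'fraction' must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  labs <- c("KII", "KIII", "KIV")
  k <- matrix(0L, nrow(per_dam), 3, dimnames = list(NULL, labs))
  for (i in seq_len(nrow(per_dam))) {
    dvec <- as.integer(unlist(per_dam[i, paste0("d_", labs)]))
    nd <- sum(dvec)
    n_k <- round(fraction * nd)
    if (n_k > 0) {
      pick <- sample(rep(labs, dvec), n_k)
      k[i, ] <- vapply(labs, function(l) sum(pick == l), 0L)
    }
  }
  per_dam$k_KII <- k[, "KII"]; per_dam$k_KIII <- k[, "KIII"]
  per_dam$k_KIV <- k[, "KIV"]
  per_dam
}
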