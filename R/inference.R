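# Maximum-likelihood machinery formalizing the observed-vs-expected
# comparison of progeny counts: a binomial factor for offspring sexing and a
# conditional multinomial factor for the karyotyped-daughter subsample.

.FREE_PARAMS <- c("wY_KII", "wY_KIII", "wY_KIV", "v_X1X1", "s_KII", "s_KIII")
.DAUGHTER_LABELS <- c("KII", "KIII", "KIV")

#' Progeny count tables
#'
#' Aggregated breeding outcomes per dam karyomorph: number of dams, sexed
#' sons and daughters, and karyomorph counts among the karyotyped subsample
#' of daughters (columns \code{k_KII}, \code{k_KIII}, \code{k_KIV}).  The
#' karyotyped counts may cover only part of the daughters, as in the colony
#' data where 64 of 196 daughters were karyotyped.
#'
#' @param x a data frame with columns \code{dam_karyomorph}, \code{n_dams},
#'   \code{n_sons}, \code{n_daughters} and optionally \code{k_KII},
#'   \code{k_KIII}, \code{k_KIV} (missing k-columns default to 0).  Rows with
#'   the same dam karyomorph are pooled.
#' @return An object of class \code{"progeny_counts"} (a data frame with one
#'   row per dam karyomorph).
#' @examples
#' progeny_counts(data.frame(dam_karyomorph = "KII", n_dams = 17,
#'                           n_sons = 54, n_daughters = 95,
#'                           k_KII = 9, k_KIII = 25, k_KIV = 3))
#' @export
progeny_counts <- function(x) {
  x <- as.data.frame(x)
  need <- c("dam_karyomorph", "n_sons", "n_daughters")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"n_dams" %in% names(x)) x$n_dams <- rep(1L, nrow(x))
  for (k in paste0("k_", .DAUGHTER_LABELS))
    if (!k %in% names(x)) x[[k]] <- rep(0L, nrow(x))
  cols <- c("n_dams", "n_sons", "n_daughters", paste0("k_", .DAUGHTER_LABELS))
  if (!all(x$dam_karyomorph %in% c("KII", "KIII", "KIV")))
    stop("dam_karyomorph must be one of KII, KIII, KIV", call. = FALSE)
  num <- as.matrix(x[cols])
  if (anyNA(num) || any(num < 0) || any(num != round(num)))
    stop("counts must be non-negative integers", call. = FALSE)
  bad <- rowSums(x[paste0("k_", .DAUGHTER_LABELS)]) > x$n_daughters
  if (any(bad))
    stop("karyotyped daughters exceed n_daughters for dam karyomorph ",
         paste(x$dam_karyomorph[bad], collapse = ", "), call. = FALSE)
  if (nrow(x) == 0L) {
    out <- cbind(data.frame(dam_karyomorph = character(0)), x[cols])
    return(structure(out, class = c("progeny_counts", "data.frame")))
  }
  out <- stats::aggregate(x[cols], by = list(dam_karyomorph = x$dam_karyomorph),
                          FUN = sum)
  out <- out[order(out$dam_karyomorph), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("progeny_counts", "data.frame"))
}

#' @export
print.progeny_counts <- function(x, ...) {
  cat("<progeny counts>\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Log-likelihood of progeny counts under a cross model
#'
#' For each dam karyomorph the likelihood factorizes into (i) a binomial term
#' for the number of sons among all sexed offspring, with success probability
#' \code{\link{expected_sex_ratio}}, and (ii) a multinomial term for the
#' karyomorphs of the karyotyped daughters, with probabilities
#' \code{\link{daughter_karyomorph_distribution}}.  Karyotyping covers only a
#' subsample of daughters, so the multinomial is conditional on a daughter
#' being karyotyped (simple random subsampling leaves the class distribution
#' unchanged).  An observed class with model probability zero yields
#' \code{-Inf}: the hypothesis is rejected by an impossible observation.
#'
#' @param counts a \code{\link{progeny_counts}} object (or coercible data
#'   frame); may be empty, giving log-likelihood 0.
#' @inheritParams cross
#' @return The log-likelihood (a single number, \code{<= 0} or \code{-Inf}).
#' @examples
#' pc <- load_fixture("progeny")
#' cross_log_likelihood(pc, "mech_a")
#' cross_log_likelihood(pc, "standard")   # -Inf: impossible daughters observed
#' @export
cross_log_likelihood <- function(counts, hypothesis = "mech_a",
                                 params = cross_params()) {
  if (is.null(counts) || nrow(as.data.frame(counts)) == 0L) return(0)
  counts <- progeny_counts(counts)
  hypothesis <- match_hypothesis(hypothesis)
  ll <- 0
  for (i in seq_len(nrow(counts))) {
    dam <- counts$dam_karyomorph[i]
    d <- cross(dam, "KI", hypothesis, params)
    n <- counts$n_sons[i] + counts$n_daughters[i]
    if (n > 0) {
      p_male <- sum(d$norm_p[d$sex == "male"])
      ll <- ll + stats::dbinom(counts$n_sons[i], n, p_male, log = TRUE)
    }
    kvec <- as.numeric(unlist(counts[i, paste0("k_", .DAUGHTER_LABELS)]))
    if (sum(kvec) > 0) {
      f <- d$sex == "female" & d$viable
      pf <- sum(d$norm_p[f])
      pvec <- vapply(.DAUGHTER_LABELS, function(l)
        sum(d$norm_p[f & d$karyomorph == l]) / pf, 0)
      ll <- ll + log_multinom(kvec, pvec)
    }
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

# multinomial log-pmf with the 0 * log(0) = 0 convention
log_multinom <- function(x, p) {
  if (any(x > 0 & p == 0)) return(-Inf)
  use <- x > 0
  lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x[use] * log(p[use]))
}

free_param_bounds <- function(name) {
  if (grepl("^wY_", name)) c(1e-3, 1e3) else c(0, 1)
}

param_grid <- function(name, lower, upper, n) {
  if (grepl("^wY_", name)) exp(seq(log(lower), log(upper), length.out = n))
  else seq(lower, upper, length.out = n)
}

#' Fit cross parameters by maximum likelihood
#'
#' Maximizes \code{\link{cross_log_likelihood}} over a chosen set of free
#' parameters by deterministic bounded grid refinement: each sweep scans each
#' free parameter on a grid over its current interval (log-spaced over
#' [1e-3, 1e3] for sperm weights, linear over [0, 1] otherwise), moves to the
#' best point, and shrinks the interval around it.  The procedure is exactly
#' reproducible; no randomness is involved.  Profile-likelihood 95% intervals
#' are computed by scanning each free parameter over its full range and
#' re-optimizing the others, using the chi-square(1) cutoff of 1.92
#' log-likelihood units.
#'
#' @inheritParams cross_log_likelihood
#' @param free character vector of free parameters, a subset of
#'   \code{c("wY_KII", "wY_KIII", "wY_KIV", "v_X1X1", "s_KII", "s_KIII")}.
#' @param start a \code{\link{cross_params}} object giving the values of the
#'   fixed parameters (and start of the free ones).
#' @param grid_points points per grid scan.
#' @param sweeps refinement sweeps.
#' @param profile if \code{TRUE} (default), compute profile intervals.
#' @return An object of class \code{"neoxy_fit"}: a list with
#'   \code{estimates}, \code{logL}, \code{intervals} (matrix of profile
#'   bounds), \code{params} (full parameter object at the optimum),
#'   \code{hypothesis} and \code{convergence} metadata, including a
#'   \code{non_identifiable} flag raised when the likelihood is flat over
#'   the initial grid.
#' @examples
#' pc <- load_fixture("progeny")
#' fit_parameters(pc, "mech_a", free = "wY_KII", profile = FALSE)
#' @export
fit_parameters <- function(counts, hypothesis = "mech_a",
                           free = c("wY_KII", "wY_KIII"),
                           start = cross_params(), grid_points = 25L,
                           sweeps = 8L, profile = TRUE) {
  hypothesis <- match_hypothesis(hypothesis)
  free <- unique(free)
  bad <- setdiff(free, .FREE_PARAMS)
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- progeny_counts(counts)

  obj <- function(vals) {
    cross_log_likelihood(counts, hypothesis, set_params(start, vals))
  }

  opt <- grid_refine(obj, free, grid_points, sweeps)

  # identifiability screen on the initial full-range grid, one parameter at
  # a time with the others at their estimates
  flat <- vapply(free, function(nm) {
    b <- free_param_bounds(nm)
    g <- param_grid(nm, b[1], b[2], grid_points)
    ll <- vapply(g, function(v) {
      vals <- opt$estimates; vals[nm] <- v; obj(vals)
    }, 0)
    fin <- ll[is.finite(ll)]
    length(fin) == 0L || diff(range(fin)) < 1e-8
  }, NA)

  intervals <- NULL
  if (profile && length(free)) {
    intervals <- matrix(NA_real_, length(free), 2,
                        dimnames = list(free, c("lower", "upper")))
    cutoff <- opt$logL - stats::qchisq(0.95, 1) / 2
    for (nm in free) {
      b <- free_param_bounds(nm)
      g <- param_grid(nm, b[1], b[2], 61L)
      others <- setdiff(free, nm)
      prof <- vapply(g, function(v) {
        if (length(others)) {
          obj2 <- function(vals) {
            vv <- c(vals, stats::setNames(v, nm))
            obj(vv)
          }
          grid_refine(obj2, others, 15L, 4L)$logL
        } else obj(stats::setNames(v, nm))
      }, 0)
      keep <- g[prof >= cutoff]
      keep <- c(keep, opt$estimates[[nm]])
      intervals[nm, ] <- range(keep)
    }
  }

  structure(list(estimates = opt$estimates, logL = opt$logL,
                 intervals = intervals,
                 params = set_params(start, opt$estimates),
                 hypothesis = hypothesis, free = free,
                 convergence = list(sweeps = sweeps,
                                    grid_points = grid_points,
                                    non_identifiable = flat)),
            class = "neoxy_fit")
}

# deterministic coordinate-wise grid refinement of an objective to maximize
grid_refine <- function(obj, free, grid_points, sweeps) {
  if (!length(free)) return(list(estimates = numeric(0), logL = obj(numeric(0))))
  lower <- vapply(free, function(nm) free_param_bounds(nm)[1], 0)
  upper <- vapply(free, function(nm) free_param_bounds(nm)[2], 0)
  est <- stats::setNames((lower + upper) / 2, free)
  est[grepl("^wY_", free)] <- 1  # geometric midpoint of the log-spaced range
  best_ll <- obj(est)
  for (s in seq_len(sweeps)) {
    for (nm in free) {
      g <- param_grid(nm, lower[[nm]], upper[[nm]], grid_points)
      ll <- vapply(g, function(v) {
        vals <- est; vals[nm] <- v; obj(vals)
      }, 0)
      i <- which.max(ll)
      if (is.finite(ll[i]) && ll[i] >= best_ll) {
        est[nm] <- g[i]; best_ll <- ll[i]
      }
      # shrink interval around the best grid point
      ilo <- max(1L, i - 2L); ihi <- min(length(g), i + 2L)
      lower[[nm]] <- g[ilo]; upper[[nm]] <- g[ihi]
    }
  }
  list(estimates = est, logL = best_ll)
}

#' @export
print.neoxy_fit <- function(x, ...) {
  cat("<maximum-likelihood fit> hypothesis '", x$hypothesis, "'\n", sep = "")
  cat("  logL =", format(x$logL, digits = 6), "\n")
  if (length(x$estimates)) {
    for (nm in names(x$estimates)) {
      ci <- if (!is.null(x$intervals) && nm %in% rownames(x$intervals))
        sprintf("  [%.4g, %.4g]", x$intervals[nm, 1], x$intervals[nm, 2])
      else ""
      flag <- if (isTRUE(x$convergence$non_identifiable[[nm]]))
        "  (flat likelihood: not identifiable)" else ""
      cat(sprintf("  %-8s = %.4g%s%s\n", nm, x$estimates[[nm]], ci, flag))
    }
  }
  invisible(x)
}

#' Compare sex-determination hypotheses on progeny data
#'
#' Evaluates (or fits) each hypothesis on the same progeny counts and ranks
#' them by AIC (= 2k - 2 logL, k the number of free parameters).  A
#' hypothesis under which any observed class has probability zero receives
#' log-likelihood \code{-Inf}, is flagged \code{"rejected by impossible
#' observation"}, and ranks last.  With no free parameters the comparison is
#' a pure likelihood ranking (k = 0).
#'
#' @inheritParams cross_log_likelihood
#' @param hyps character vector of at least two hypothesis ids.
#' @param params a single \code{\link{cross_params}} object, or a named list
#'   of one per hypothesis.
#' @param free \code{NULL} for no fitting, or a character vector (or named
#'   list per hypothesis) of parameters to fit by
#'   \code{\link{fit_parameters}}.
#' @return A data frame of class \code{"hypothesis_comparison"} with columns
#'   \code{hypothesis}, \code{n_par}, \code{logL}, \code{AIC},
#'   \code{rejected} and \code{note}, sorted by AIC with rejected hypotheses
#'   last.
#' @examples
#' compare_hypotheses(load_fixture("progeny"),
#'                    c("standard", "mech_a", "mech_b"))
#' @export
compare_hypotheses <- function(counts, hyps = hypotheses(),
                               params = cross_params(), free = NULL) {
  if (length(hyps) < 2L)
    stop("need at least two hypotheses to compare", call. = FALSE)
  hyps <- vapply(hyps, match_hypothesis, "")
  rows <- lapply(hyps, function(h) {
    p <- if (inherits(params, "cross_params")) params else params[[h]]
    f <- if (is.list(free)) free[[h]] else free
    if (is.null(f) || !length(f)) {
      ll <- cross_log_likelihood(counts, h, p)
      k <- 0L
    } else {
      fit <- fit_parameters(counts, h, free = f, start = p, profile = FALSE)
      ll <- fit$logL
      k <- length(f)
    }
    rejected <- !is.finite(ll)
    data.frame(hypothesis = h, n_par = k, logL = ll,
               AIC = if (rejected) Inf else 2 * k - 2 * ll,
               rejected = rejected,
               note = if (rejected) "rejected by impossible observation" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rejected, out$AIC), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hypothesis_comparison", "data.frame"))
}

#' @export
print.hypothesis_comparison <- function(x, ...) {
  cat("<hypothesis comparison> (sorted by AIC)\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}
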