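#' Cross parameters
#'
#' Parameter set for the segregation and fertilization model.
#'
#' Dams whose sex complex forms a trivalent at meiosis (KII: neo-X1 -- neo-X2
#' -- neo-X3; KIII: neo-Y -- neo-X2 -- neo-X3) resolve it by alternate
#' (balanced) segregation into exactly two gamete classes; \code{s_KII} and
#' \code{s_KIII} are the probabilities of the class carrying neo-X1
#' (respectively neo-X2).  \code{w_Y} gives, per dam karyomorph, the relative
#' fertilization success of neo-Y-bearing over neo-X1-bearing sperm: the
#' transmission-ratio-distortion knob.  It is applied at fertilization,
#' conditioned on the dam's karyomorph, because the reported sperm-class
#' success depends on the karyomorph of the fertilized female.  The viability
#' model supplies zygote viability weights, including the relative viability
#' \code{v_X1X1} of double-neo-X1 zygotes.
#'
#' @param w_Y named numeric vector of non-negative sperm weights, one per dam
#'   karyomorph (\code{KII}, \code{KIII}, \code{KIV}); a single unnamed value
#'   is recycled.
#' @param s_KII,s_KIII trivalent segregation probabilities in [0, 1].
#' @param v_X1X1 relative viability of double-neo-X1 zygotes, in [0, 1].
#' @return An object of class \code{"cross_params"}.
#' @examples
#' cross_params()                      # Mendelian defaults: no distortion
#' cross_params(w_Y = c(KII = 2.5))    # Y sperm favored in KII dams
#' @export
cross_params <- function(w_Y = 1, s_KII = 0.5, s_KIII = 0.5, v_X1X1 = 1) {
  dams <- c("KII", "KIII", "KIV")
  w <- c(KII = 1, KIII = 1, KIV = 1)
  if (length(w_Y) == 1L && is.null(names(w_Y))) {
    w[] <- w_Y
  } else {
    if (!all(names(w_Y) %in% dams))
      stop("names of 'w_Y' must be among KII, KIII, KIV", call. = FALSE)
    w[names(w_Y)] <- w_Y
  }
  if (any(!is.finite(w)) || any(w < 0))
    stop("'w_Y' weights must be finite and non-negative", call. = FALSE)
  for (s in c(s_KII, s_KIII))
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0 || s > 1)
      stop("segregation probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(w_Y = w, s_KII = s_KII, s_KIII = s_KIII, v_X1X1 = v_X1X1),
            class = "cross_params")
}

#' @export
print.cross_params <- function(x, ...) {
  cat("<cross parameters>\n")
  cat("  w_Y (Y-sperm weight by dam):",
      paste(names(x$w_Y), format(x$w_Y), sep = "=", collapse = ", "), "\n")
  cat("  s_KII =", format(x$s_KII), " s_KIII =", format(x$s_KIII),
      " v_X1X1 =", format(x$v_X1X1), "\n")
  invisible(x)
}

# A karyomorph's complement as seen by a hypothesis' bookkeeping: the full
# sex complex under the XY-female mechanisms, but only the identifiable
# large elements under the standard hypothesis, where KIII's neo-Y counts as
# an unidentified small acrocentric (KIII = a single neo-X2, hence female).
karyomorph_view <- function(karyomorph, hypothesis) {
  z <- .KARYOMORPH_TABLE[[karyomorph]]$complement
  if (hypothesis == "standard") {
    std <- switch(karyomorph,
      KI = c(X1 = 1L, X2 = 0L, X3 = 0L, Y = 1L),
      KII = c(X1 = 1L, X2 = 1L, X3 = 0L, Y = 0L),
      KIII = c(X1 = 0L, X2 = 1L, X3 = 0L, Y = 0L),
      KIV = c(X1 = 2L, X2 = 0L, X3 = 0L, Y = 0L))
    return(structure(std, class = "sex_complement"))
  }
  structure(z, class = "sex_complement")
}

# Update a cross_params object from a named vector of free-parameter values
# ("wY_KII", "wY_KIII", "wY_KIV", "v_X1X1", "s_KII", "s_KIII").
set_params <- function(params, values) {
  for (nm in names(values)) {
    v <- unname(values[[nm]])
    if (grepl("^wY_", nm)) {
      params$w_Y[[sub("^wY_", "", nm)]] <- v
    } else if (nm %in% c("v_X1X1", "s_KII", "s_KIII")) {
      params[[nm]] <- v
    } else stop("unknown parameter '", nm, "'", call. = FALSE)
  }
  params
}

#' Gamete distributions
#'
#' Enumerates the gamete classes of a karyomorph under balanced segregation.
#' Two regimes exist.  Under any XY-female mechanism the full sex complex is
#' tracked: a KI male makes \{neo-X1, neo-X3\} and \{neo-Y, neo-X3\} sperm
#' (weighted 1 : w_Y at fertilization, not here); a KII dam's trivalent
#' resolves into \{neo-X1, neo-X3\} (probability \code{s_KII}) or \{neo-X2\};
#' a KIII dam's into \{neo-X2\} (probability \code{s_KIII}) or \{neo-X3,
#' neo-Y\}; a KIV dam makes only \{neo-X1, neo-X3\} (two homomorphic
#' bivalents).  Under the standard hypothesis the unidentifiable small
#' acrocentrics are dropped, mirroring the neo-X1/0-style bookkeeping: KI male
#' \{neo-X1\} or \{neo-Y\}; KII dam \{neo-X1\} or \{neo-X2\}; KIII dam
#' \{neo-X2\} or a nullosomic gamete; KIV dam \{neo-X1\}.
#'
#' @param karyomorph a karyomorph label, \code{"KI"} to \code{"KIV"}.
#' @param sex \code{"male"} or \code{"female"}; must agree with the
#'   hypothesis' phenotype for that karyomorph.
#' @param params a \code{\link{cross_params}} object.
#' @inheritParams hypotheses
#' @return An object of class \code{"gamete_distribution"}: a data frame with
#'   columns \code{gamete} (canonical string), \code{prob}, and
#'   \code{y_bearing}, plus the complements in \code{attr(, "complements")}.
#' @examples
#' gametes("KII", "female", cross_params(), "mech_a")
#' @export
gametes <- function(karyomorph, sex, params = cross_params(),
                    hypothesis = "mech_a") {
  hypothesis <- match_hypothesis(hypothesis)
  if (!karyomorph %in% names(.KARYOMORPH_TABLE))
    stop("unsupported karyomorph '", karyomorph,
         "': gamete tables exist for KI-KIV only", call. = FALSE)
  sex <- match.arg(sex, c("male", "female"))
  expected <- phenotype(karyomorph_view(karyomorph, hypothesis), hypothesis)
  if (!identical(sex, expected))
    stop(karyomorph, " is ", expected, " under hypothesis '", hypothesis, "'",
         call. = FALSE)
  std <- hypothesis == "standard"
  cmp <- function(...) sex_complement(...)
  g <- switch(karyomorph,
    KI = if (std) list(cmp(X1 = 1), cmp(Y = 1))
         else list(cmp(X1 = 1, X3 = 1), cmp(Y = 1, X3 = 1)),
    KII = if (std) list(cmp(X1 = 1), cmp(X2 = 1))
          else list(cmp(X1 = 1, X3 = 1), cmp(X2 = 1)),
    KIII = if (std) list(cmp(X2 = 1), cmp())
           else list(cmp(X2 = 1), cmp(X3 = 1, Y = 1)),
    KIV = if (std) list(cmp(X1 = 1)) else list(cmp(X1 = 1, X3 = 1)))
  prob <- switch(karyomorph,
    KI = c(0.5, 0.5),
    KII = c(params$s_KII, 1 - params$s_KII),
    KIII = c(params$s_KIII, 1 - params$s_KIII),
    KIV = 1)
  out <- data.frame(gamete = vapply(g, format, ""),
                    prob = prob,
                    y_bearing = vapply(g, function(z) z[["Y"]] >= 1L, NA),
                    stringsAsFactors = FALSE)
  structure(out, complements = g, class = c("gamete_distribution", "data.frame"))
}

#' Offspring distribution of a dam x sire cross
#'
#' Forms the product of the dam's and sire's gamete distributions, applies
#' the fertilization weight \code{w_Y[dam]} to neo-Y-bearing sperm, labels
#' every zygote with its karyomorph and phenotypic sex under the hypothesis,
#' attaches viability weights, and renormalizes over viable zygotes.  The
#' only supported sire is KI, the single male karyomorph observed.
#'
#' @param dam dam karyomorph: \code{"KII"}, \code{"KIII"} or \code{"KIV"}.
#' @param sire sire karyomorph; must be \code{"KI"}.
#' @inheritParams gametes
#' @return An object of class \code{"offspring_distribution"}: a data frame
#'   with columns \code{zygote}, \code{karyomorph}, \code{sex}, \code{raw_p}
#'   (pre-selection zygote probability, sums to 1), \code{viability}
#'   (weight in [0, 1]), \code{viable} (logical) and \code{norm_p}
#'   (probability among surviving offspring, sums to 1 over viable rows).
#' @examples
#' cross("KII", "KI", "mech_a")   # four viable classes at 25% each
#' cross("KIII", "KI", "standard")  # 75% of zygote mass is lethal
#' @export
cross <- function(dam, sire = "KI", hypothesis = "mech_a",
                  params = cross_params()) {
  hypothesis <- match_hypothesis(hypothesis)
  if (!identical(sire, "KI"))
    stop("unsupported cross: the only male karyomorph is KI", call. = FALSE)
  if (!dam %in% c("KII", "KIII", "KIV"))
    stop("unsupported cross: dam must be one of KII, KIII, KIV", call. = FALSE)
  dam_sex <- phenotype(karyomorph_view(dam, hypothesis), hypothesis)
  if (dam_sex != "female")
    stop(dam, " is not female under hypothesis '", hypothesis, "'",
         call. = FALSE)

  dg <- gametes(dam, "female", params, hypothesis)
  sg <- gametes(sire, "male", params, hypothesis)
  # fertilization-stage sperm selection, conditioned on the dam karyomorph
  w <- params$w_Y[[dam]]
  sperm_p <- sg$prob * ifelse(sg$y_bearing, w, 1)
  sperm_p <- sperm_p / sum(sperm_p)

  model <- viability_model(hypothesis, v_X1X1 = params$v_X1X1)
  dcmp <- attr(dg, "complements"); scmp <- attr(sg, "complements")
  rows <- list()
  for (i in seq_along(dcmp)) for (j in seq_along(scmp)) {
    z <- dcmp[[i]] + scmp[[j]]
    lab <- if (hypothesis == "standard") classify_karyomorph_std(z)
           else classify_karyomorph(z)
    rows[[length(rows) + 1L]] <- data.frame(
      zygote = format(z), karyomorph = lab,
      sex = phenotype(z, hypothesis),
      raw_p = dg$prob[i] * sperm_p[j],
      viability = viability_weight(z, model),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # aggregate identical zygote classes
  out <- stats::aggregate(raw_p ~ zygote + karyomorph + sex + viability,
                          data = out, FUN = sum)
  out$viable <- out$viability > 0
  m <- out$raw_p * out$viability
  out$norm_p <- if (sum(m) > 0) m / sum(m) else 0
  out <- out[order(-out$norm_p, out$zygote),
             c("zygote", "karyomorph", "sex", "raw_p", "viability",
               "viable", "norm_p")]
  rownames(out) <- NULL
  structure(out, dam = dam, sire = sire, hypothesis = hypothesis,
            params = params,
            class = c("offspring_distribution", "data.frame"))
}

#' @export
print.offspring_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("<offspring distribution> %s dam x %s sire, hypothesis '%s'\n",
              attr(x, "dam"), attr(x, "sire"), attr(x, "hypothesis")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summary quantities of a cross
#'
#' \code{expected_sex_ratio()} gives the proportion of males among viable
#' (surviving) offspring; \code{nonviable_fraction()} the raw zygote
#' probability mass falling in strictly lethal classes;
#' \code{daughter_karyomorph_distribution()} the distribution of karyomorphs
#' among surviving daughters.
#'
#' @inheritParams cross
#' @return A single proportion, or for
#'   \code{daughter_karyomorph_distribution()} a named probability vector
#'   over daughter karyomorph labels.
#' @examples
#' expected_sex_ratio("KII", "KI", "mech_a")    # 0.25
#' expected_sex_ratio("KIII", "KI", "mech_a")   # 1/3
#' nonviable_fraction("KIII", "KI", "standard") # 0.75
#' daughter_karyomorph_distribution("KIII", "KI", "standard")  # all KII
#' @export
expected_sex_ratio <- function(dam, sire = "KI", hypothesis = "mech_a",
                               params = cross_params()) {
  d <- cross(dam, sire, hypothesis, params)
  sum(d$norm_p[d$sex == "male"])
}

#' @rdname expected_sex_ratio
#' @export
nonviable_fraction <- function(dam, sire = "KI", hypothesis = "mech_a",
                               params = cross_params()) {
  d <- cross(dam, sire, hypothesis, params)
  sum(d$raw_p[!d$viable])
}

#' @rdname expected_sex_ratio
#' @export
daughter_karyomorph_distribution <- function(dam, sire = "KI",
                                             hypothesis = "mech_a",
                                             params = cross_params()) {
  d <- cross(dam, sire, hypothesis, params)
  f <- d[d$sex == "female" & d$viable, ]
  p <- tapply(f$norm_p, f$karyomorph, sum)
  p <- p / sum(p)
  # stable label order
  labs <- intersect(c("KI", "KII", "KIII", "KIV", "UNLISTED"), names(p))
  p[labs]
}
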