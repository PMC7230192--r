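# Internal element keys, in canonical sort order (X1 < X2 < X3 < Y).
.ELEMENTS <- c("X1", "X2", "X3", "Y")
.ELEMENT_LABELS <- c(X1 = "neo-X1", X2 = "neo-X2", X3 = "neo-X3", Y = "neo-Y")

# Element composition table: which elements carry functional X euchromatin and
# which translocated autosomal block.  The neo-Y's X-homologous material is
# repeats only (no synteny to the X by sequencing), so it counts as 0 X.
#   A1 = block homologous to MAG13/MMU18 (q-arm of neo-X1, body of neo-Y)
#   A2 = block homologous to MAG17/19   (arm of neo-X2, body of neo-X3)
.ELEMENT_HAS_X <- c(X1 = TRUE, X2 = TRUE, X3 = FALSE, Y = FALSE)
.ELEMENT_BLOCK <- c(X1 = "A1", X2 = "A2", X3 = "A2", Y = "A1")

#' Sex-chromosome complements
#'
#' A sex complement is a multiset of the four sex-complex chromosomes of
#' \emph{Lasiopodomys mandarinus vinogradovi}: neo-X1 (large metacentric,
#' X euchromatin + autosomal block A1), neo-X2 (X euchromatin + block A2),
#' neo-X3 (small acrocentric, block A2 only) and neo-Y (small acrocentric,
#' block A1 plus X-homologous repeats only).  It is represented as a named
#' non-negative integer vector of copy numbers.
#'
#' @param X1,X2,X3,Y copy numbers (each at most 2; at most 4 elements total).
#' @return An object of class \code{"sex_complement"}: a named integer vector
#'   with elements \code{X1}, \code{X2}, \code{X3}, \code{Y}.
#' @examples
#' sex_complement(X1 = 1, Y = 1, X3 = 2)       # the male karyomorph KI
#' as_complement("neo-X2/neo-X3/neo-Y")        # KIII, parsed from a string
#' @export
sex_complement <- function(X1 = 0L, X2 = 0L, X3 = 0L, Y = 0L) {
  z <- c(X1 = as.integer(X1), X2 = as.integer(X2),
         X3 = as.integer(X3), Y = as.integer(Y))
  validate_complement(z)
  structure(z, class = "sex_complement")
}

validate_complement <- function(z) {
  if (anyNA(z) || any(z < 0L))
    stop("complement copy numbers must be non-negative integers", call. = FALSE)
  if (any(z > 2L))
    stop("no sex-complex element occurs in more than two copies", call. = FALSE)
  if (sum(z) > 4L)
    stop("a sex complement holds at most four elements", call. = FALSE)
  invisible(z)
}

#' @rdname sex_complement
#' @param x a \code{sex_complement}, a named count vector, or a string such as
#'   \code{"neo-X1/neo-X3/neo-X3/neo-Y"} (element order is free; \code{"0"}
#'   denotes an empty complement).
#' @export
as_complement <- function(x) {
  if (inherits(x, "sex_complement")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- trimws(x)
    if (x == "" || x == "0")
      return(sex_complement())
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts <- parts[parts != "0"]  # the paper's "neo-X1/0" style bookkeeping
    key <- names(.ELEMENT_LABELS)[match(parts, .ELEMENT_LABELS)]
    # also accept bare keys "X1".."Y"
    bare <- is.na(key) & parts %in% .ELEMENTS
    key[bare] <- parts[bare]
    if (anyNA(key))
      stop("unknown chromosome element in '", x, "'", call. = FALSE)
    tab <- table(factor(key, levels = .ELEMENTS))
    return(sex_complement(tab[["X1"]], tab[["X2"]], tab[["X3"]], tab[["Y"]]))
  }
  if (is.numeric(x)) {
    z <- c(X1 = 0L, X2 = 0L, X3 = 0L, Y = 0L)
    if (is.null(names(x)) && length(x) == 4L) {
      z[] <- as.integer(x)
    } else {
      if (!all(names(x) %in% .ELEMENTS))
        stop("complement names must be among X1, X2, X3, Y", call. = FALSE)
      z[names(x)] <- as.integer(x)
    }
    validate_complement(z)
    return(structure(z, class = "sex_complement"))
  }
  stop("cannot interpret 'x' as a sex complement", call. = FALSE)
}

#' @rdname sex_complement
#' @param ... ignored.
#' @export
format.sex_complement <- function(x, ...) {
  if (sum(x) == 0L) return("0")
  paste(rep(.ELEMENT_LABELS[.ELEMENTS], unclass(x)[.ELEMENTS]), collapse = "/")
}

#' @export
print.sex_complement <- function(x, ...) {
  cat("<sex complement> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`+.sex_complement` <- function(e1, e2) {
  z <- unclass(as_complement(e1)) + unclass(as_complement(e2))
  validate_complement(z)
  structure(z, class = "sex_complement")
}

# The four observed karyomorphs.  KI is the universal male form; KII-KIV are
# the three female forms (KIV reconstructed, never painted directly).
.KARYOMORPH_TABLE <- list(
  KI   = list(complement = c(X1 = 1L, X2 = 0L, X3 = 2L, Y = 1L), diploid = 48L),
  KII  = list(complement = c(X1 = 1L, X2 = 1L, X3 = 1L, Y = 0L), diploid = 47L),
  KIII = list(complement = c(X1 = 0L, X2 = 1L, X3 = 1L, Y = 1L), diploid = 47L),
  KIV  = list(complement = c(X1 = 2L, X2 = 0L, X3 = 2L, Y = 0L), diploid = 48L)
)

#' Karyomorph definitions and classification
#'
#' \code{karyomorph()} returns the full description of one of the four
#' karyomorphs observed in the species (KI: neo-X1/neo-X3/neo-X3/neo-Y males,
#' 2n = 48; KII: neo-X1/neo-X2/neo-X3 females, 2n = 47; KIII:
#' neo-X2/neo-X3/neo-Y females, 2n = 47; KIV: neo-X1/neo-X1/neo-X3/neo-X3
#' females, 2n = 48).  \code{classify_karyomorph()} maps an arbitrary
#' complement back to its karyomorph label, or \code{"UNLISTED"} for any
#' combination outside the four observed ones (unobserved zygote classes are
#' classified, not rejected, so the cross engine can enumerate them).
#'
#' @param label one of \code{"KI"}, \code{"KII"}, \code{"KIII"}, \code{"KIV"}.
#' @return \code{karyomorph()}: a list with \code{label}, \code{complement}
#'   and \code{diploid_number}; \code{classify_karyomorph()}: a character
#'   label.
#' @examples
#' classify_karyomorph(as_complement("neo-X1/neo-Y/neo-X3/neo-X3"))  # "KI"
#' classify_karyomorph(sex_complement(X2 = 2))                       # "UNLISTED"
#' @export
karyomorph <- function(label) {
  label <- match.arg(label, names(.KARYOMORPH_TABLE))
  k <- .KARYOMORPH_TABLE[[label]]
  list(label = label,
       complement = structure(k$complement, class = "sex_complement"),
       diploid_number = k$diploid)
}

#' @rdname karyomorph
#' @param complement a \code{\link{sex_complement}} (or anything
#'   \code{\link{as_complement}} accepts).
#' @export
classify_karyomorph <- function(complement) {
  z <- as_complement(complement)
  for (lab in names(.KARYOMORPH_TABLE))
    if (identical(unclass(z), .KARYOMORPH_TABLE[[lab]]$complement))
      return(lab)
  "UNLISTED"
}

# Karyomorph labelling used in the standard-hypothesis bookkeeping, where
# gametes carry only the identifiable sex elements (neo-X1, neo-X2, Y) and the
# small acrocentrics are dropped ("neo-X1/0" style).  Labels are assigned from
# the large-element content alone.
classify_karyomorph_std <- function(complement) {
  z <- unclass(as_complement(complement))
  if (z[["X1"]] == 1L && z[["Y"]] == 1L && z[["X2"]] == 0L) return("KI")
  if (z[["X1"]] == 1L && z[["X2"]] == 1L && z[["Y"]] == 0L) return("KII")
  if (z[["X2"]] == 1L && sum(z) == 1L) return("KIII")
  if (z[["X1"]] == 2L && z[["X2"]] == 0L && z[["Y"]] == 0L && sum(z) == 2L)
    return("KIV")
  "UNLISTED"
}

#' Chromosomal dosage of a complement
#'
#' Counts functional X-euchromatin copies and copies of each translocated
#' autosomal block across the elements of a complement.  Block A1 is the
#' MAG13/MMU18 homolog (q-arm of neo-X1 and the body of neo-Y); block A2 is
#' the MAG17/19 homolog (arm of neo-X2 and body of neo-X3).  The neo-Y
#' contributes no X dosage: its X-homologous FISH signal is repetitive
#' sequence with no X synteny by sequencing.
#'
#' @inheritParams classify_karyomorph
#' @return A named integer vector \code{c(nX, nA1, nA2)}.
#' @examples
#' dosage(karyomorph("KIII")$complement)  # single functional X: c(1, 1, 2)
#' @export
dosage <- function(complement) {
  z <- unclass(as_complement(complement))
  c(nX  = sum(z[.ELEMENT_HAS_X[.ELEMENTS]]),
    nA1 = sum(z[.ELEMENT_BLOCK[.ELEMENTS] == "A1"]),
    nA2 = sum(z[.ELEMENT_BLOCK[.ELEMENTS] == "A2"]))
}

.HYPOTHESES <- c("standard", "mech_a", "mech_b", "mech_c")

#' Sex-determination hypotheses
#'
#' Four genotype-to-sex maps are modelled.  \code{"standard"} is conventional
#' Y-dominant sex determination: male if and only if a neo-Y is present.  The
#' three XY-female mechanisms all make neo-X2/neo-Y carriers female:
#' \describe{
#'   \item{\code{"mech_a"}}{neo-X2 carries an epistatic locus (B) suppressing
#'     the dominant male trigger (A) on the neo-Y; male iff neo-Y present and
#'     neo-X2 absent.}
#'   \item{\code{"mech_b"}}{neo-X1 carries a locus (D) complementing the male
#'     trigger (C) on the neo-Y, the locus being absent/inactive on neo-X2;
#'     male iff neo-Y and neo-X1 both present.}
#'   \item{\code{"mech_c"}}{the male trigger sits on neo-X1 itself and is
#'     inactive both in double dose and in the presence of neo-X2; male iff
#'     exactly one neo-X1 and no neo-X2.}
#' }
#'
#' @param hypothesis one of \code{"standard"}, \code{"mech_a"},
#'   \code{"mech_b"}, \code{"mech_c"} (case-insensitive).
#' @return \code{hypotheses()} returns the vector of valid hypothesis ids.
#' @export
hypotheses <- function() .HYPOTHESES

match_hypothesis <- function(hypothesis) {
  match.arg(tolower(hypothesis), .HYPOTHESES)
}

#' @rdname hypotheses
#' @inheritParams classify_karyomorph
#' @return \code{phenotype()} returns \code{"male"} or \code{"female"}.
#' @examples
#' phenotype("neo-X2/neo-X3/neo-Y", "mech_a")    # "female": suppressed trigger
#' phenotype("neo-X2/neo-X3/neo-Y", "standard")  # "male": Y present
#' @export
phenotype <- function(complement, hypothesis) {
  z <- unclass(as_complement(complement))
  hypothesis <- match_hypothesis(hypothesis)
  male <- switch(hypothesis,
    standard = z[["Y"]] >= 1L,
    mech_a   = z[["Y"]] >= 1L && z[["X2"]] == 0L,
    mech_b   = z[["Y"]] >= 1L && z[["X1"]] >= 1L,
    mech_c   = z[["X1"]] == 1L && z[["X2"]] == 0L)
  if (male) "male" else "female"
}

#' Zygote viability models
#'
#' Constructs the viability model attached to a sex-determination hypothesis.
#' Under any XY-female mechanism the only strictly nonviable combination is
#' the zygote with no X euchromatin at all (operationally: neither neo-X1 nor
#' neo-X2 -- the neo-Y/neo-Y class).  Under the standard hypothesis the
#' lethality assumptions needed to rescue it are encoded: zygotes with no
#' X-bearing element, neo-X2/neo-Y males, and monosomic zygotes carrying a
#' single sex element (the neo-X1/0 and neo-Y/0 products of a nullosomic
#' gamete).  An optional relative viability \code{v_X1X1} in [0, 1] applies
#' to neo-X1/neo-X1 (double neo-X1) zygotes under either regime, encoding the
#' proposed lower viability of KIV females.
#'
#' @inheritParams hypotheses
#' @param v_X1X1 relative viability of zygotes carrying two neo-X1 copies.
#' @return An object of class \code{"viability_model"}.
#' @examples
#' viability_weight("neo-X3/neo-X3/neo-Y/neo-Y", viability_model("mech_a"))  # 0
#' @export
viability_model <- function(hypothesis = "mech_a", v_X1X1 = 1) {
  hypothesis <- match_hypothesis(hypothesis)
  if (!is.numeric(v_X1X1) || length(v_X1X1) != 1L || is.na(v_X1X1) ||
      v_X1X1 < 0 || v_X1X1 > 1)
    stop("'v_X1X1' must be a single number in [0, 1]", call. = FALSE)
  structure(list(regime = if (hypothesis == "standard") "standard" else "xy_female",
                 hypothesis = hypothesis, v_X1X1 = v_X1X1),
            class = "viability_model")
}

#' @rdname viability_model
#' @inheritParams classify_karyomorph
#' @param model a \code{viability_model}.
#' @return \code{viability_weight()} returns a weight in [0, 1]: 0 for lethal
#'   classes, \code{v_X1X1} for double-neo-X1 zygotes, 1 otherwise.
#' @export
viability_weight <- function(complement, model) {
  stopifnot(inherits(model, "viability_model"))
  z <- unclass(as_complement(complement))
  no_x <- z[["X1"]] == 0L && z[["X2"]] == 0L
  lethal <- if (model$regime == "standard") {
    no_x || (z[["X2"]] >= 1L && z[["Y"]] >= 1L) || sum(z) == 1L
  } else {
    no_x
  }
  if (lethal) return(0)
  if (z[["X1"]] >= 2L) return(model$v_X1X1)
  1
}
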