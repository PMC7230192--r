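# TSV I/O, packaged fixtures of the published colony data, and report
# writing.  All tables are UTF-8 TSV with "." as the decimal separator and
# the karyomorph labels KI-KIV as canonical strings.

.PROGENY_COLS <- c("dam_id", "dam_karyomorph", "sire_karyomorph",
                   "n_sons", "n_daughters")
.K_COLS <- c("k_KII", "k_KIII", "k_KIV")

#' Read and write progeny tables
#'
#' The progeny TSV schema has header columns \code{dam_id},
#' \code{dam_karyomorph}, \code{sire_karyomorph}, \code{n_sons},
#' \code{n_daughters}, optionally \code{n_dams} (for pooled rows; defaults
#' to 1) and \code{k_KII}, \code{k_KIII}, \code{k_KIV} (karyotyped-daughter
#' counts, defaulting to 0).  Validation failures report the offending line
#' and column.
#'
#' @param path file path.
#' @return \code{read_progeny_table()} returns the pooled
#'   \code{\link{progeny_counts}}; the raw per-row table is attached as
#'   attribute \code{"rows"}.
#' @examples
#' path <- system.file("extdata", "progeny.tsv", package = "neoxy")
#' read_progeny_table(path)
#' @export
read_progeny_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.PROGENY_COLS, names(x))
  if (length(miss))
    stop("progeny table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"n_dams" %in% names(x)) x$n_dams <- rep(1L, nrow(x))
  for (k in .K_COLS) if (!k %in% names(x)) x[[k]] <- rep(0L, nrow(x))
  for (i in seq_len(nrow(x))) {
    line <- i + 1L  # header is line 1
    if (!x$dam_karyomorph[i] %in% c("KII", "KIII", "KIV"))
      stop(sprintf("%s line %d, column dam_karyomorph: unknown karyomorph '%s'",
                   path, line, x$dam_karyomorph[i]), call. = FALSE)
    if (!x$sire_karyomorph[i] %in% "KI")
      stop(sprintf("%s line %d, column sire_karyomorph: sires must be KI, got '%s'",
                   path, line, x$sire_karyomorph[i]), call. = FALSE)
    for (cc in c("n_dams", "n_sons", "n_daughters", .K_COLS)) {
      v <- x[[cc]][i]
      if (is.na(v) || !is.numeric(v) || v < 0 || v != round(v))
        stop(sprintf("%s line %d, column %s: negative or non-integer count",
                     path, line, cc), call. = FALSE)
    }
    if (sum(unlist(x[i, .K_COLS])) > x$n_daughters[i])
      stop(sprintf("%s line %d: karyotyped daughters exceed n_daughters",
                   path, line), call. = FALSE)
  }
  out <- progeny_counts(x)
  attr(out, "rows") <- x
  out
}

#' @rdname read_progeny_table
#' @param x a per-dam data frame with the schema columns, or a
#'   \code{\link{progeny_counts}} object (written as pooled rows).
#' @export
write_progeny_table <- function(x, path) {
  if (inherits(x, "progeny_counts")) {
    x <- data.frame(dam_id = paste0(x$dam_karyomorph, "_pooled"),
                    dam_karyomorph = x$dam_karyomorph,
                    sire_karyomorph = "KI", n_dams = x$n_dams,
                    n_sons = x$n_sons, n_daughters = x$n_daughters,
                    k_KII = x$k_KII, k_KIII = x$k_KIII, k_KIV = x$k_KIV,
                    stringsAsFactors = FALSE)
  }
  keep <- intersect(c(.PROGENY_COLS[1:3], "n_dams", .PROGENY_COLS[4:5],
                      .K_COLS), names(x))
  utils::write.table(x[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.FIXTURES <- c("progeny", "daughter_karyomorphs", "individuals",
               "female_cohort")

#' Packaged colony datasets
#'
#' Small published datasets from the mandarin vole breeding colony, shipped
#' as plain TSV under \code{inst/extdata}:
#' \describe{
#'   \item{\code{"progeny"}}{pooled progeny counts per dam karyomorph (17
#'     KII dams: 54 sons / 95 daughters, karyotyped daughters 9 KII / 25
#'     KIII / 3 KIV; 18 KIII dams: 70 / 101, karyotyped 21 / 6 / 0; 3 KIV
#'     dams: 7 sons / 0 daughters), as a \code{\link{progeny_counts}}
#'     object.}
#'   \item{\code{"daughter_karyomorphs"}}{the karyotyped-daughter counts as
#'     a 2 x 3 matrix (rows: KII and KIII dams; columns KII/KIII/KIV), the
#'     input of the 2 x 3 Fisher exact test.}
#'   \item{\code{"individuals"}}{the 12 animals studied by molecular
#'     cytogenetics: abbreviation, 2n, origin (7 laboratory, 5 wild), sex
#'     complement string and the LMAN2 autosome morph (2a/2b/2c).}
#'   \item{\code{"female_cohort"}}{the reproductive-success cohort: 13 KII,
#'     15 KIII and 4 KIV females; breeder counts are only published for KIV
#'     (0 of 4), the others are NA.}
#' }
#'
#' @param name one of \code{"progeny"}, \code{"daughter_karyomorphs"},
#'   \code{"individuals"}, \code{"female_cohort"}.
#' @return The dataset; class depends on \code{name} (see above).
#' @examples
#' load_fixture("daughter_karyomorphs")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1L || !name %in% .FIXTURES)
    stop("unknown fixture '", name, "'; available: ",
         paste(.FIXTURES, collapse = ", "), call. = FALSE)
  path <- function(f) system.file("extdata", f, package = "neoxy",
                                  mustWork = TRUE)
  switch(name,
    progeny = read_progeny_table(path("progeny.tsv")),
    daughter_karyomorphs = {
      pc <- read_progeny_table(path("progeny.tsv"))
      m <- as.matrix(pc[pc$dam_karyomorph %in% c("KII", "KIII"), .K_COLS])
      dimnames(m) <- list(c("KII_dams", "KIII_dams"),
                          c("KII", "KIII", "KIV"))
      m
    },
    individuals = utils::read.delim(path("individuals.tsv"),
                                    stringsAsFactors = FALSE),
    female_cohort = utils::read.delim(path("female_cohort.tsv"),
                                      stringsAsFactors = FALSE))
}

#' Write a deterministic analysis report
#'
#' Writes any tabular analysis result (offspring distribution, hypothesis
#' comparison, trajectory, ...) to disk with stable column order, fixed
#' float formatting and a metadata header, so identical inputs give
#' byte-identical files.
#'
#' @param results a data frame (or object convertible to one).
#' @param path output file.
#' @param format \code{"tsv"} (metadata as \code{# key: value} comment
#'   lines) or \code{"text"} (aligned human-readable table).
#' @param metadata named list echoed into the header (seeds, parameters,
#'   ...).
#' @return \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_report(cross("KII", "KI", "mech_a"), f,
#'              metadata = list(dam = "KII", hypothesis = "mech_a"))
#' @export
write_report <- function(results, path, format = c("tsv", "text"),
                         metadata = list()) {
  format <- match.arg(format)
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(v) formatC(v, format = "g",
                                                 digits = 10))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(list(generated_by = paste0("neoxy ",
                as.character(utils::packageVersion("neoxy")))), metadata)
  for (nm in names(hdr))
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(hdr[[nm]]), collapse = " ")), con)
  if (format == "tsv") {
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(utils::capture.output(print(df, row.names = FALSE)), con)
  }
  invisible(path)
}
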