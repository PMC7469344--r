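#' Read an lncRNA-disease association pair list
#'
#' Reads a delimited two-column file of \code{lncRNA<sep>disease} identifier
#' pairs. Duplicate pairs are dropped (with a message stating how many);
#' otherwise row order is preserved, which fixes the downstream entity
#' indexing.
#'
#' @param path path to the pair file.
#' @param sep field separator, tab by default.
#' @return a data.frame with character columns \code{lncRNA} and
#'   \code{disease}, one row per distinct pair.
#' @examples
#' tf <- tempfile()
#' writeLines(c("l1\td1", "l2\td1", "l2\td2"), tf)
#' readAssociationPairs(tf)
#' @export
readAssociationPairs <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("association file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no pairs: association file is empty")
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, function(p) length(p) < 2 ||
                        !nzchar(trimws(p[1])) || !nzchar(trimws(p[2])), logical(1)))
  if (length(bad))
    stop(sprintf("malformed association row(s) at line %s: need 2 non-empty fields",
                 paste(bad, collapse = ", ")))
  df <- data.frame(lncRNA = trimws(vapply(parts, `[`, "", 1)),
                   disease = trimws(vapply(parts, `[`, "", 2)),
                   stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) message(sum(dup), " duplicate pair(s) removed")
  df[!dup, , drop = FALSE]
}

#' Build the binary interaction matrix from a pair list
#'
#' Constructs the diseases x lncRNAs adjacency matrix (1 where the pair is in
#' the list). Entity order is first appearance in the pair list, or
#' lexicographic with \code{sortIds = TRUE}.
#'
#' @param pairs data.frame with columns \code{lncRNA}, \code{disease} (as
#'   returned by [readAssociationPairs()]).
#' @param sortIds sort identifiers lexicographically instead of keeping
#'   first-appearance order.
#' @return an \linkS4class{InteractionMatrix}.
#' @examples
#' pairs <- data.frame(lncRNA = c("l1", "l2", "l2"),
#'                     disease = c("d1", "d1", "d2"))
#' buildInteractionMatrix(pairs)
#' @export
buildInteractionMatrix <- function(pairs, sortIds = FALSE) {
  stopifnot2(nrow(pairs) > 0, "empty pair list")
  ds <- unique(pairs$disease)
  ls <- unique(pairs$lncRNA)
  if (sortIds) { ds <- sort(ds); ls <- sort(ls) }
  m <- matrix(0, length(ds), length(ls), dimnames = list(ds, ls))
  m[cbind(match(pairs$disease, ds), match(pairs$lncRNA, ls))] <- 1
  new("InteractionMatrix", assoc = m)
}

#' Read a MeSH-style disease hierarchy file
#'
#' Each row maps a disease name to one dot-delimited tree code
#' (\code{disease<TAB>code}); a disease may appear on several rows. Disease
#' names are keyed case-insensitively with whitespace collapsed, so that
#' association identifiers and hierarchy rows match under the same rule.
#' Malformed codes are skipped with a warning naming the line.
#'
#' @param path path to the hierarchy file.
#' @param sep field separator, tab by default.
#' @return a \linkS4class{DiseaseHierarchy}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("glioma\tC04.557.465", "glioma\tC04.588"), tf)
#' readHierarchy(tf)
#' @export
readHierarchy <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  records <- list()
  for (i in seq_along(lines)) {
    p <- strsplit(lines[i], sep, fixed = TRUE)[[1]]
    if (length(p) < 2 || !nzchar(trimws(p[1]))) {
      warning(sprintf("hierarchy line %d malformed, skipped", i)); next
    }
    code <- trimws(p[2])
    if (!grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", code)) {
      warning(sprintf("hierarchy line %d: malformed tree code '%s', skipped", i, code))
      next
    }
    key <- normalizeDiseaseKey(p[1])
    records[[key]] <- unique(c(records[[key]], code))
  }
  new("DiseaseHierarchy", records = records)
}

#' Diseases of an interaction matrix lacking hierarchy records
#'
#' @param interaction an \linkS4class{InteractionMatrix}.
#' @param hierarchy a \linkS4class{DiseaseHierarchy}.
#' @return character vector of disease identifiers with no semantic record.
#' @export
unmappedDiseases <- function(interaction, hierarchy) {
  d <- diseaseNames(interaction)
  d[!(normalizeDiseaseKey(d) %in% names(hierarchy@records))]
}

#' Write / read a labelled matrix as TSV
#'
#' Interchange format for every matrix the package produces: a header row of
#' column labels, a first column of row labels, reals printed with 12
#' significant digits. Reading back reproduces values exactly at that
#' precision.
#'
#' @param m a matrix with dimnames (or an \linkS4class{InteractionMatrix}).
#' @param path output file.
#' @return \code{readMatrixTSV} returns the matrix with dimnames restored.
#' @examples
#' tf <- tempfile()
#' m <- matrix(pi * 1:4 / 7, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
#' writeMatrixTSV(m, tf)
#' max(abs(readMatrixTSV(tf) - m))
#' @export
writeMatrixTSV <- function(m, path) {
  if (is(m, "InteractionMatrix")) m <- m@assoc
  stopifnot2(!is.null(rownames(m)) && !is.null(colnames(m)),
             "matrix must have dimnames")
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], sprintf("%.12g", m[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file needs a header and >= 1 row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncols <- length(header) - 1
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != ncols + 1)
  if (length(bad)) stop("matrix row/header shape mismatch at data row ",
                        paste(bad, collapse = ", "))
  m <- matrix(as.numeric(unlist(lapply(rows, `[`, -1))), length(rows), ncols,
              byrow = TRUE,
              dimnames = list(vapply(rows, `[`, "", 1), header[-1]))
  if (any(is.na(m))) stop("non-numeric matrix entries")
  m
}
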