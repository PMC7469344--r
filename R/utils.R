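# internal helpers

sigmoid <- function(z) 1 / (1 + exp(-z))

# evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# disease-name key used to match association identifiers to hierarchy records:
# case-insensitive, internal whitespace collapsed
normalizeDiseaseKey <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

stopifnot2 <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

checkSquareSymmetric <- function(m, label) {
  stopifnot2(nrow(m) == ncol(m), sprintf("%s must be square", label))
  stopifnot2(max(abs(m - t(m))) < 1e-10, sprintf("%s must be symmetric", label))
  invisible(TRUE)
}
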