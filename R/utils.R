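# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All user-facing randomness in the package flows through this helper so that
# identical seeds give identical output regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of an ACGTN (+ IUPAC W) string, vectorised.
revcomp <- function(x) {
  chartr("ACGTNW", "TGCANW", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

# IUPAC symbol -> regex character class (only the symbols enzymes here use).
iupac_to_regex <- function(site) {
  map <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]")
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, names(map))
  if (length(unknown)) {
    stop("unsupported recognition symbol(s): ", paste(unknown, collapse = ", "))
  }
  paste(map[chars], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
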