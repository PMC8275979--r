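# Internal helpers shared across modules.

# The 15-letter IUPAC nucleotide alphabet (U is normalized to T on ingest).
IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

# Evaluate code() under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards so library calls do not
# perturb user-level randomness. seed = NULL runs under the ambient RNG.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code())
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  code()
}

# Deterministic per-record sub-seed so each record gets its own stream.
# Kept below 2^31 - 1 (R integers are 32-bit).
.deriveSeed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 99991) %% 2147483647)
}

# Coerce a single sequence (character scalar, DNAString, or length-1
# DNAStringSet) to one plain character string.
.asSingleString <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(x)
  }
  if (is(x, "XString")) return(as.character(x))
  if (is(x, "XStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence")
    return(as.character(x[[1L]]))
  }
  stop("unsupported sequence type: ", class(x)[1L])
}

# Coerce to DNAStringSet, preserving names.
.asSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "XString")) return(Biostrings::DNAStringSet(as.character(x)))
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("unsupported sequence type: ", class(x)[1L])
}
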