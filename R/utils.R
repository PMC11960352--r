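# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is restored afterwards so generator calls never perturb each other.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# One master seed, one deterministic sub-stream per named stage. Kept below
# 2^31 so the result is always a valid R integer seed; changing e.g. the
# number of spins never perturbs the bootstrap stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.double(seed)) * 7919 + h * 104729) %% 2147483587)
}

read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# full-precision decimal rendering so written doubles round-trip
fmt_full <- function(x) sprintf("%.17g", x)

sample_sd <- function(x) stats::sd(x)

stop_msg <- function(...) stop(..., call. = FALSE)
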