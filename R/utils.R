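# Internal helpers shared across modules.

# Canonical string key for a directed pair; "\r" cannot occur in gene IDs
# read from CSV so the key is collision-free.
.edgeKey <- function(from, to) paste(from, to, sep = "\r")

.keyToPairs <- function(keys) {
  if (!length(keys))
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1L),
             to = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

# Deterministic sub-seed so independent stages draw from independent streams
# while all flowing from one user-visible seed; kept below 2^31 - 1.
.deriveSeed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Run an expression under a local RNG state: seeds deterministically and
# restores the caller's RNG afterwards.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Numerically stable log(1 + exp(x)).
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
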