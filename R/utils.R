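# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that fixture generation does not
#' perturb a caller's random stream.
#' @param seed integer seed.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Derive an independent child seed stream per submodule so that adding one
# fixture type does not perturb the others. Kept below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483629)
}

# Largest-remainder allocation of n items over proportions; deterministic,
# ties broken by position.
alloc_counts <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0))
  if (abs(sum(props) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * props
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0) {
    o <- order(raw - base, seq_along(raw), decreasing = c(TRUE, FALSE),
               method = "radix")
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  out <- as.integer(base)
  names(out) <- names(props)
  out
}

# Sample `n` distinct 1-based positions uniformly from the union of closed
# intervals [starts, ends]. Intervals are assumed disjoint.
sample_positions <- function(starts, ends, n) {
  if (n == 0L) return(integer(0))
  widths <- ends - starts + 1
  if (any(widths <= 0)) stop("degenerate interval")
  total <- sum(widths)
  if (n > total) {
    stop(sprintf("cannot place %d distinct positions in %d available bases",
                 n, total))
  }
  offs <- sort(sample.int(total, n))
  cum <- cumsum(widths)
  idx <- findInterval(offs - 1, cum) + 1L
  starts[idx] + (offs - (cum[idx] - widths[idx]) - 1)
}

# Complement of disjoint sorted closed intervals within [1, len].
complement_intervals <- function(starts, ends, len) {
  if (length(starts) == 0L) return(data.frame(start = 1, end = len))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  gs <- c(1, ends + 1)
  ge <- c(starts - 1, len)
  keep <- ge >= gs
  data.frame(start = gs[keep], end = ge[keep])
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Significance stars used throughout phenotype comparisons:
# 0.01 < P <= 0.05 -> *, 0.001 < P <= 0.01 -> **, P <= 0.001 -> ***.
star_category <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
         ifelse(p <= 0.05, "*", "ns")))
  out[is.na(p)] <- NA_character_
  out
}
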