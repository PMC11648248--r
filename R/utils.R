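# Internal helpers shared across modules.

.PADDY_METHODS <- c("MT", "MD", "MAT", "MAD")
.BENEFIT_COLS  <- c("yield", "ghg", "eb", "pfp", "eue")
.INPUT_COLS    <- c("n_rate", "p_rate", "k_rate", "seed_rate")
.COHORT_COLS   <- c("method", "n_rate", "p_rate", "k_rate", "seed_rate",
                    "herbicide", "pesticide", "labor_hours", "machine_hours",
                    "grain_yield")

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed error so callers can distinguish schema/validation/lookup failures
pd_stop <- function(msg, class = "paddyopt_error", call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "paddyopt_error", "error"),
                      call = call))
}

# Run `code` under a fixed RNG state, restoring the caller's stream afterwards.
# Mersenne-Twister + inversion are pinned so seeded output is platform-stable.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Normal truncated at zero via resampling; at the CVs used here the truncation
# mass is negligible, so the sample mean stays at `mean`.
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- which(x < 0)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  x[x < 0] <- 0
  x
}

# md5 of a serialized object, for provenance headers
config_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
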