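## Internal helpers shared across modules.

## Deterministic 32-bit sub-seed from a base seed and a character tag, so a
## pipeline stage's draws do not depend on which other stages ran before it.
subSeed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

## Evaluate expr with a local RNG state seeded by `seed`; restores the
## caller's RNG afterwards so generators do not disturb each other.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## NB sampler parameterized by mean and dispersion alpha (var = mu+alpha mu^2);
## alpha = 0 falls back to Poisson.
rcounts <- function(n, mu, alpha) {
  mu <- pmax(mu, 0)
  if (alpha <= 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

## Sample per-cell library sizes: gamma with squared CV = disp (fixed if 0).
rlibsize <- function(n, mean, disp) {
  if (disp <= 1e-12) rep(mean, n) else rgamma(n, shape = 1 / disp,
                                              scale = mean * disp)
}

stopifnot2 <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
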