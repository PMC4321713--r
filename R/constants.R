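# Physical constants used throughout. Boltzmann constant in the two unit
# systems of the pipeline (pN nm for single-molecule forces, kJ/mol for
# molecular free energies) and the conversion between them.
.kB_pN_nm <- 0.0138065       # pN nm / K
.kB_kJ_mol <- 0.0083145      # kJ / (mol K)
.pN_per_kJ_mol_nm <- 1.6606  # 1 kJ mol^-1 nm^-1 expressed in pN

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG stream is restored afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

.assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  as.numeric(x)
}
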