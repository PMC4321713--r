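# Shared fixtures built in code.

# Free-energy profile of a WLC in kJ/mol: closed-form integral of the
# Marko-Siggia force. Used to build mean-force-shaped synthetic PMFs.
wlc_pmf_fun <- function(lp_nm, lc_nm, temperature_K = 300) {
  kB_pN <- 0.0138065
  kB_kJ <- 0.0083145
  kBT <- kB_pN * temperature_K
  function(z) {
    u <- pmin(pmax(z, 0) / lc_nm, 1 - 1e-9)
    (kBT / lp_nm) * lc_nm * (0.25 / (1 - u) - u / 4 + u^2 / 2 - 0.25) *
      kB_kJ / kB_pN
  }
}

gauss_curve <- function(x, center, fwhm, amp)
  amp * exp(-4 * log(2) * (x - center)^2 / fwhm^2)
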