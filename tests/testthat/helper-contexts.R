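# Shared fixtures, built once per test run. The astigmatism strength is the
# standard calibration used throughout: w6 = 0.11 * lambda = 74.8 nm RMS.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

default_cfg <- function() fixture("cfg", function() optical_config())

astig_coeffs <- function() zernike_coefficients(`6` = 0.11 * 680)

no_coeffs <- function() zernike_coefficients()

# noise-free expected image for a given state (signal only, unit photons)
expected_image <- function(state, coeffs = astig_coeffs(), n_eff = 5e5,
                           background = 0, oversampling = 9) {
  n_eff * unclass(psf_image(state, default_cfg(), coeffs,
                            oversampling = oversampling)) + background
}

# shared fit table for the in-plane diagonal dipole, astigmatic context
table_pi2 <- function() {
  fixture("table_pi2", function() {
    psf_table(pi / 2, pi / 4, default_cfg(), astig_coeffs())
  })
}
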