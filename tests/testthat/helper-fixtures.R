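# shared fixtures: small domains are expensive enough to build once
pure_well <- function() fe_params(chi = 0, c_rep = 0, rho_R = 1)

tiny_domain <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- build_domain(radius = 6, dx = 0.4)
    d
  }
})

small_domain <- local({
  d <- NULL
  function() {
    if (is.null(d)) d <<- build_domain(radius = 10, dx = 0.4)
    d
  }
})

# annulus protein field: dense ring between r_in and r_out
annulus_field <- function(domain, r_in, r_out, phi_dense = 0.7,
                          phi_dilute = 0.1) {
  r <- sqrt(domain$x^2 + domain$y^2)
  ifelse(r >= r_in & r <= r_out, phi_dense, phi_dilute)
}

disk_field <- function(domain, R, phi_dense = 0.7, phi_dilute = 0.1,
                       center = c(0, 0)) {
  r <- sqrt((domain$x - center[1])^2 + (domain$y - center[2])^2)
  ifelse(r <= R, phi_dense, phi_dilute)
}
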