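# Shared fixtures. All synthetic inputs are generated in code, seeded.

# kinetic constants used throughout the flux-law checks
fig_params <- function() transporter_params(k2 = 4, k4 = 4, Kd = 10, et = 10)

# localization benchmark image spec: dim background so that both signatures
# of nuclear concentration (nuclear tail and cytoplasmic depletion) are
# detectable; geometry fixed across the suite
bench_spec <- function(f, seed) image_spec(f = f, b = 10, seed = seed)

# pre-starvation reference pooled over four f = 0 frames
bench_reference <- function(q = 0.995, seeds = 101:104) {
  imgs <- lapply(seeds, function(s) make_cell_image(bench_spec(0, s)))
  build_reference(lapply(imgs, `[[`, "frame"), q = q,
                  masks = lapply(imgs, `[[`, "mask"))
}

# closed-form internal concentration for k2 = k4 carriers: the flux
# denominator is constant, so J = (et k2 / 2) (theta_o - theta_i) and
# theta_i = theta_o - 2 J / (et k2); independent oracle for the bisection
analytic_internal_k2eqk4 <- function(p, J, s_out, model = "carrier") {
  to <- s_out / (p$Kd + s_out)
  ti <- if (model == "carrier") to - 2 * J / (p$et * p$k2) else
    to - J / (p$et * p$k2)
  if (ti < 0) return(NA_real_)
  p$Kd * ti / (1 - ti)
}
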