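# Toy fixtures with hand-checkable round numbers.

toy_catheter <- function(...) {
  args <- list(name = "Toy", v_res = 0.5, e_b = 2, v_dead = 0.1, tau = 0.2,
               v_u0 = 0.5, c_u = 0.05, k_u = 2, v_o0 = 1.5, c_o = 0.03,
               recommended_min = 0.5, recommended_max = 2.0)
  do.call(catheter_spec, utils::modifyList(args, list(...)))
}

toy_eso <- function(e_es = 2) esophagus_spec(e_es = e_es)

noise_free_cfg <- function(...) {
  args <- list(noise_sd = 0)
  do.call(bench_config, utils::modifyList(args, list(...)))
}
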