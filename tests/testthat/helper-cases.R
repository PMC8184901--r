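# memoised end-to-end runs shared between the pipeline and acceptance tests
vd_case_cache <- new.env(parent = emptyenv())

vd_case <- function(key, cfg_fun) {
  if (is.null(vd_case_cache[[key]])) vd_case_cache[[key]] <- run_case(cfg_fun())
  vd_case_cache[[key]]
}

vd_ai_run <- function() vd_case("ai", function()
  case_config(vd_spec, method = "ai"))

vd_expert_run <- function() vd_case("expert_ct", function()
  case_config(vd_spec, method = "expert_ct"))

vd_shifted_spec <- function() default_phantom(
  misalignment_mm = rep(list(c(0, 0, 8)), 4))

vd_shift3_run <- function() vd_case("shift3", function()
  case_config(vd_shifted_spec(), method = "expert_ct", margin_mm = 3))

vd_shift6_run <- function() vd_case("shift6", function()
  case_config(vd_shifted_spec(), method = "expert_ct", margin_mm = 6))
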