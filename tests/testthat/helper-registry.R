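# Shared fixtures: load the registry once per test run; small builders used
# across files.

reg <- load_registry()

minimal_link <- function() {
  build_entity(reg, "Link", list(Name = "BossDB", URI = "https://bossdb.org"))
}

small_bundle <- function(seed = 1, c = 1, e = 1, k = 1) {
  generate_bundle(reg, fixture_recipe(seed, c, e, k))
}

error_codes <- function(report) {
  errs <- Filter(function(v) v$severity == "error", report$violations)
  vapply(errs, `[[`, "", "rule_code")
}

error_paths <- function(report) {
  errs <- Filter(function(v) v$severity == "error", report$violations)
  vapply(errs, `[[`, "", "entity_path")
}
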