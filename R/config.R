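# Pipeline configuration: every threshold used by a run, serialized verbatim
# into every report.

#' Pipeline configuration
#'
#' Defaults follow the published protocol: up to 30 retrosynthesis proposals
#' of which at most 7 curated reactant sets are kept, reaction-center radius
#' 2, candidate Tanimoto threshold 0.4 and an MCS heavy-atom-ratio scaffold
#' threshold of 2/3.
#'
#' @param n_retro maximum retro proposals per input (default 30).
#' @param k_keep curated reactant sets kept per input (default 7).
#' @param center_radius reaction-center environment radius (default 2).
#' @param sim_threshold candidate Tanimoto threshold (default 0.4).
#' @param mcs_threshold MCS heavy-atom-ratio threshold (default 2/3).
#' @param fp_params fingerprint settings: `radius` (2) and `nbits` (2048).
#' @param db_profile database curation profile label recorded in reports.
#' @param candidate_cap per-reaction candidate cap (0 = unlimited).
#' @param mcs_time_budget per-pair MCS budget in seconds (default 10).
#' @param center_strictness center-query strictness: `"loose"`, `"default"`
#'   or `"strict"`.
#' @param curation_rules reactant-set curation rules to apply (see
#'   [curate_reactant_sets()]).
#' @param seed integer seed for seeded operations (diversity picking,
#'   fixtures).
#' @return validated config object (class `aa_config`).
#' @export
aa_config <- function(n_retro = 30L, k_keep = 7L, center_radius = 2L,
                      sim_threshold = 0.4, mcs_threshold = 2 / 3,
                      fp_params = default_fp_params(),
                      db_profile = "zinc_style", candidate_cap = 0L,
                      mcs_time_budget = 10,
                      center_strictness = "default",
                      curation_rules = c("parseable", "multi_reactant",
                                         "product_identity", "dedup",
                                         "round_trip"),
                      seed = 42L) {
  cfg <- structure(list(
    n_retro = as.integer(n_retro), k_keep = as.integer(k_keep),
    center_radius = as.integer(center_radius),
    sim_threshold = sim_threshold, mcs_threshold = mcs_threshold,
    fp_params = fp_params, db_profile = db_profile,
    candidate_cap = as.integer(candidate_cap),
    mcs_time_budget = mcs_time_budget,
    center_strictness = center_strictness,
    curation_rules = curation_rules,
    seed = as.integer(seed)), class = "aa_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "aa_config")) stop_config("cfg must come from aa_config()")
  with(cfg, {
    if (n_retro < 1L) stop_config("n_retro must be >= 1")
    if (k_keep < 1L) stop_config("k_keep must be >= 1")
    if (center_radius < 0L) stop_config("center_radius must be >= 0")
    if (sim_threshold < 0 || sim_threshold > 1) stop_config("sim_threshold must be in [0,1]")
    if (mcs_threshold <= 0 || mcs_threshold > 1) stop_config("mcs_threshold must be in (0,1]")
    if (candidate_cap < 0L) stop_config("candidate_cap must be >= 0")
    if (!center_strictness %in% c("loose", "default", "strict")) {
      stop_config("unknown center_strictness")
    }
  })
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [aa_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return `aa_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(aa_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(aa_config, vals)
}

# Flat, JSON-friendly snapshot embedded in every report.
config_snapshot <- function(cfg) {
  list(
    n_retro = cfg$n_retro, k_keep = cfg$k_keep,
    center_radius = cfg$center_radius,
    sim_threshold = cfg$sim_threshold, mcs_threshold = cfg$mcs_threshold,
    fp_radius = cfg$fp_params$radius, fp_nbits = cfg$fp_params$nbits,
    db_profile = cfg$db_profile, candidate_cap = cfg$candidate_cap,
    mcs_time_budget = cfg$mcs_time_budget,
    center_strictness = cfg$center_strictness,
    curation_rules = cfg$curation_rules,
    seed = cfg$seed)
}
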