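#' Read an ensemble specification from a YAML config
#'
#' Key-value mirror of [ensemble_spec()]: `structures` is either a path to a
#' dot-bracket file (resolved relative to the config) or an inline list of
#' records with `dotbracket` and optional `sequence`/`name`; `weights`,
#' `p_open`, `p_closed`, `probed`, `missing_tail` and `seed` map directly;
#' `stat_alt_p_below` / `stat_null_p_below` parameterize the two
#' [stat_distribution()]s.
#'
#' @param path YAML file path.
#' @return An [ensemble_spec()].
#' @export
read_ensemble_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$structures)) {
    abort("config must name structures", class = "smstruct_format_error")
  }
  structures <- if (is.character(cfg$structures) &&
                    length(cfg$structures) == 1) {
    db_path <- cfg$structures
    if (!file.exists(db_path)) {
      db_path <- file.path(dirname(path), cfg$structures)
    }
    read_structures(db_path)
  } else {
    lapply(cfg$structures, function(rec) {
      parse_dotbracket(rec$dotbracket, sequence = rec$sequence,
                       name = rec$name)
    })
  }
  ensemble_spec(
    structures,
    weights = cfg$weights,
    p_open = cfg$p_open %||% 0.5,
    p_closed = cfg$p_closed %||% 0.15,
    probed = cfg$probed,
    stat_alt = stat_distribution(cfg$stat_alt_p_below %||% 0.95),
    stat_null = stat_distribution(cfg$stat_null_p_below %||% 0.15),
    missing_tail = cfg$missing_tail %||% 13L,
    seed = cfg$seed %||% 1L
  )
}
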