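#' The Parkinson's-disease telehealth needs hierarchy
#'
#' The decision tree developed for telehealth systems that monitor, assess
#' and help manage Parkinson's disease: 5 categories (Performance, User
#' experience, Clinical practice, Economic, Technical issues) holding 17 user
#' needs. Labels keep the original up/down arrows ("↑ wearability
#' acceptance"); ids normalize them to `increase_`/`decrease_` prefixes so
#' files and columns stay ASCII.
#'
#' @return An [hierarchy()] with 5 categories and 17 leaves.
#' @examples
#' h <- pd_fixture()
#' length(leaves(h))
#' names(comparison_sets(h))
#' @export
pd_fixture <- function() {
  load_hierarchy(system.file("extdata", "pd_hierarchy.yaml",
                             package = "ahpneeds", mustWork = TRUE))
}

#' Published reference weights for the PD telehealth needs hierarchy
#'
#' The group-level results reported by the expert-panel study behind
#' [pd_fixture()] (16 respondents: 10 technical, 6 clinical): consolidated
#' global and local weights per need, category weights, subgroup medians, and
#' the between-group t-test p-values, all at the 3-decimal precision at which
#' they were reported. Useful as worked-example input for
#' [propagate_global_weights()], [rank_needs()], [spearman()] and
#' [weighted_score()] when no raw judgment data are at hand.
#'
#' @return A list with two data frames: `needs` (17 rows: `need_id`,
#'   `category_id`, `gw_group`, `lw_group`, subgroup medians, t-test
#'   p-values) and `categories` (5 rows: `category_id`, `cw_group`, subgroup
#'   medians, p-value).
#' @examples
#' ref <- pd_reference_weights()
#' rank_needs(stats::setNames(ref$needs$gw_group, ref$needs$need_id))[1:3, ]
#' @export
pd_reference_weights <- function() {
  needs <- utils::read.csv(
    system.file("extdata", "pd_reference_weights_needs.csv",
                package = "ahpneeds", mustWork = TRUE),
    stringsAsFactors = FALSE)
  categories <- utils::read.csv(
    system.file("extdata", "pd_reference_weights_categories.csv",
                package = "ahpneeds", mustWork = TRUE),
    stringsAsFactors = FALSE)
  list(needs = needs, categories = categories)
}

#' The 16-expert panel roster
#'
#' Respondent metadata for the panel that produced
#' [pd_reference_weights()]: 10 technical and 6 clinical experts with sex and
#' years of experience (overall, with PD, with eHealth).
#'
#' @return A data frame with columns `code`, `group`, `sex`,
#'   `years_experience`, `years_pd`, `years_ehealth`.
#' @export
pd_panel <- function() {
  read_panel(system.file("extdata", "pd_panel.csv",
                         package = "ahpneeds", mustWork = TRUE))
}
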