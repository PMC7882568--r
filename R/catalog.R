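#' Game-type catalog
#'
#' A catalog binds each game type to the survey columns holding its
#' gambling-frequency category (ordinal 0-5) and its usual spending per
#' session (currency, >= 0), and records whether the type is played
#' offline or online. Column naming is catalog-driven so that survey
#' files with arbitrary headers can be bound without renaming.
#'
#' @param type_id character vector of unique short identifiers.
#' @param label human-readable game-type labels.
#' @param mode `"offline"` or `"online"` per type.
#' @param freq_column,spend_column survey column names per type; default
#'   `freq_<type_id>` and `spend_<type_id>`.
#' @return A data frame of class `"gcmm_catalog"` with columns
#'   `type_id`, `label`, `mode`, `freq_column`, `spend_column`.
#' @seealso [default_catalog()] for the 15-type catalog used throughout.
#' @export
gcmm_catalog <- function(type_id, label = type_id, mode,
                         freq_column = paste0("freq_", type_id),
                         spend_column = paste0("spend_", type_id)) {
  type_id <- as.character(type_id)
  if (anyDuplicated(type_id))
    stop("catalog type_ids must be unique", call. = FALSE)
  mode <- match.arg(mode, c("offline", "online"), several.ok = TRUE)
  mode <- rep_len(mode, length(type_id))
  if (!all(mode %in% c("offline", "online")))
    stop("mode must be 'offline' or 'online'", call. = FALSE)
  cat <- data.frame(type_id = type_id,
                    label = as.character(rep_len(label, length(type_id))),
                    mode = mode,
                    freq_column = as.character(rep_len(freq_column, length(type_id))),
                    spend_column = as.character(rep_len(spend_column, length(type_id))),
                    stringsAsFactors = FALSE)
  class(cat) <- c("gcmm_catalog", "data.frame")
  cat
}

#' Default 15-game-type catalog
#'
#' Eight offline and seven online game types as surveyed in the Icelandic
#' prevalence studies the model was developed on: lotto, electronic gaming
#' machines (EGM), scratch cards, sport-pool and fixed-odds sport betting,
#' live betting, poker, skill-game betting, bingo, and other foreign-site
#' online gambling.
#'
#' @return A `"gcmm_catalog"` with 15 rows.
#' @export
default_catalog <- function() {
  gcmm_catalog(
    type_id = c("lotto_off", "lotto_on_is", "egm_off", "scratch_off",
                "pools_off", "pools_on_is", "sport_off", "sport_on_is",
                "live_on", "sport_on_foreign", "poker_off",
                "poker_on_foreign", "skill_off", "bingo_off",
                "other_on_foreign"),
    label = c("Lotto offline",
              "Lotto online (Icelandic website)",
              "Electronic gaming machine offline",
              "Scratch cards offline",
              "Betting on sport pools offline",
              "Betting on sport pools online (Icelandic website)",
              "Sport betting offline (fixed odds)",
              "Sport betting online (Icelandic website)",
              "Live betting online (Icelandic or foreign website)",
              "Sport betting online (foreign website)",
              "Poker offline",
              "Poker online (foreign website)",
              "Betting on skill games offline",
              "Bingo offline",
              "Other online gambling (foreign websites)"),
    mode = c("offline", "online", "offline", "offline", "offline",
             "online", "offline", "online", "online", "online",
             "offline", "online", "offline", "offline", "online")
  )
}

# internal: stop unless x is a valid catalog
check_catalog <- function(catalog) {
  if (!inherits(catalog, "gcmm_catalog"))
    stop("expected a 'gcmm_catalog' (see gcmm_catalog())", call. = FALSE)
  invisible(catalog)
}

#' @export
print.gcmm_catalog <- function(x, ...) {
  cat("Game-type catalog:", nrow(x), "types (",
      sum(x$mode == "offline"), "offline,",
      sum(x$mode == "online"), "online )\n")
  print.data.frame(x[, c("type_id", "label", "mode")], row.names = FALSE)
  invisible(x)
}
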