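#' Catalog of scored social actions
#'
#' The action catalog enumerates every behavior label that may appear in a
#' bout table, together with its behavioral category. The default catalog
#' covers the standard screen of male-male and male-female fly social
#' actions: three aggressive threat actions (threat, pump, charge), contact
#' aggression (lunge, hold, tussle, headbutt, barrage), wing-borne courtship
#' (UWE, BWE, row), locomotor courtship (circle, copulation attempt), female
#' responses (ovipositor extrusion, wing spreading) and the terminal
#' copulation state.
#'
#' @param extra Optional tibble/data.frame with columns `action` and
#'   `category` appended to the default catalog (e.g. lab-specific actions).
#' @return A tibble with columns `action` (unique label) and `category`,
#'   one of `"aggression-threat"`, `"aggression-contact"`, `"courtship-wing"`,
#'   `"courtship-locomotor"`, `"female-response"`, `"terminal"`.
#' @examples
#' action_catalog()
#' @export
action_catalog <- function(extra = NULL) {
  cat <- tibble::tribble(
    ~action,               ~category,
    "threat",              "aggression-threat",
    "pump",                "aggression-threat",
    "charge",              "aggression-threat",
    "lunge",               "aggression-contact",
    "hold",                "aggression-contact",
    "tussle",              "aggression-contact",
    "headbutt",            "aggression-contact",
    "barrage",             "aggression-contact",
    "UWE",                 "courtship-wing",
    "BWE",                 "courtship-wing",
    "row",                 "courtship-wing",
    "circle",              "courtship-locomotor",
    "copulation_attempt",  "courtship-locomotor",
    "ovipositor_extrusion", "female-response",
    "wing_spreading",      "female-response",
    "copulation",          "terminal"
  )
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    stopifnot(all(c("action", "category") %in% names(extra)))
    cat <- dplyr::bind_rows(cat, extra[, c("action", "category")])
  }
  if (anyDuplicated(cat$action)) {
    stop("duplicate action labels in catalog: ",
         paste(unique(cat$action[duplicated(cat$action)]), collapse = ", "))
  }
  allowed <- c("aggression-threat", "aggression-contact", "courtship-wing",
               "courtship-locomotor", "female-response", "terminal")
  bad <- setdiff(cat$category, allowed)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  cat
}

#' Actions belonging to a behavioral super-class
#'
#' Convenience lookup for the action labels that count as "courtship"
#' (wing + locomotor) or "aggression" (threat + contact) in a catalog.
#'
#' @param catalog An [action_catalog()] tibble.
#' @param class `"courtship"` or `"aggression"`.
#' @return Character vector of action labels.
#' @export
actions_of_class <- function(catalog, class = c("courtship", "aggression")) {
  class <- match.arg(class)
  cats <- switch(class,
    courtship = c("courtship-wing", "courtship-locomotor"),
    aggression = c("aggression-threat", "aggression-contact"))
  catalog$action[catalog$category %in% cats]
}
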