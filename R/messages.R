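#' Supported interface languages
#' @export
LANGUAGES <- c("en", "es", "pt")

#' Number of congratulation message variants
#' @export
N_CONGRATULATIONS <- 3L

the_catalog <- new.env(parent = emptyenv())

#' Load the localized message catalog
#'
#' The catalog maps message keys to spoken-instruction text in English,
#' Spanish and Portuguese. It ships with the package as a JSON file
#' keyed by language then message key; a user file with the same layout
#' can override it.
#'
#' @param path optional path to an alternative catalog JSON file.
#' @return Named list: language -> (key -> text).
#' @export
message_catalog <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_catalog$default)) return(the_catalog$default)
    path <- system.file("extdata", "messages.json", package = "trunksense")
    cat_ <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    the_catalog$default <- cat_
    return(cat_)
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' All message keys the engine can emit
#' @return character vector of keys.
#' @export
message_keys <- function() {
  c("LEAN_FORWARD", "LEAN_BACKWARD", "LEAN_LEFT", "LEAN_RIGHT",
    paste0("CONGRATULATION_", seq_len(N_CONGRATULATIONS)),
    "PRAISE_MAINTAINED", "CALIBRATION_DONE")
}

#' Resolve a message key to localized text
#'
#' @param key one of [message_keys()].
#' @param language one of `"en"`, `"es"`, `"pt"`.
#' @param catalog catalog as returned by [message_catalog()].
#' @return The localized text, scalar character.
#' @examples
#' resolve_message("LEAN_BACKWARD", "en")
#' @export
resolve_message <- function(key, language, catalog = message_catalog()) {
  if (!language %in% names(catalog)) {
    stop("unknown language: ", language)
  }
  lang <- catalog[[language]]
  if (!key %in% names(lang) || !nzchar(lang[[key]])) {
    stop("unknown message key: ", key)
  }
  lang[[key]]
}
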