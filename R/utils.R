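# logit-scale helpers used by the simulator and batch adjustment
logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# The eight RAND-36 category keys, in conventional reporting order.
#' RAND-36 category column names
#'
#' Returns the names of the eight RAND-36 quality-of-life score columns
#' expected in a sample sheet (`rand36_physical_functioning`, ...,
#' `rand36_emotion`). Each holds a score in \[0, 100\].
#'
#' @return Character vector of length 8.
#' @export
rand36_cols <- function() {
  paste0("rand36_", c(
    "physical_functioning", "role_physical", "pain", "general_health",
    "energy", "social_functioning", "role_emotional", "emotion"
  ))
}

#' Closed vocabularies for probe annotation
#'
#' Genic-region and CpG-island-relation categories recognised by the
#' annotation contract.
#'
#' @return Named list with elements `genic_region` and `island_relation`.
#' @export
annotation_vocab <- function() {
  list(
    genic_region = c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                     "3'UTR", "intergenic"),
    island_relation = c("Island", "N_Shore", "S_Shore", "N_Shelf",
                        "S_Shelf", "OpenSea")
  )
}

cell_proportion_cols <- function(df) {
  grep("^cell_", names(df), value = TRUE)
}

stop_if_missing_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "gcm_schema_error")
  }
  invisible(df)
}
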