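#' Model states, eating-disorder types and sexes
#'
#' The life-course model has six states: healthy, the four DSM-5 eating
#' disorders (anorexia nervosa, bulimia nervosa, binge eating disorder, and
#' other specified feeding and eating disorders), and deceased. Deceased is
#' absorbing. States are coded as integers so that simulated histories can be
#' stored compactly; the helpers below translate between codes and labels.
#'
#' @format `ED_TYPES` and `SEXES` are character vectors; `STATE_*` are
#'   integer scalars.
#' @name model-states
NULL

#' @rdname model-states
#' @export
ED_TYPES <- c("AN", "BN", "BED", "OSFED")

#' @rdname model-states
#' @export
SEXES <- c("male", "female")

#' @rdname model-states
#' @export
STATE_HEALTHY <- 1L

#' @rdname model-states
#' @export
STATE_DECEASED <- 6L

# ED states occupy codes 2..5 in ED_TYPES order
ED_STATE_CODES <- 2:5

#' @rdname model-states
#' @export
STATE_LABELS <- c("HEALTHY", "AN", "BN", "BED", "OSFED", "DECEASED")

# Ages: annual transitions at ages 0..39, state recorded at ages 0..40.
N_AGES <- 40L

#' Is a state code an eating-disorder state?
#'
#' @param state integer state code(s) (1 = healthy, 2..5 = AN/BN/BED/OSFED,
#'   6 = deceased).
#' @return logical vector: membership in the four ED states.
#' @export
is_ed_state <- function(state) state >= 2L & state <= 5L

#' Translate between ED labels and state codes
#'
#' @param ed character vector of ED labels (`"AN"`, `"BN"`, `"BED"`,
#'   `"OSFED"`) or `"ANY"`.
#' @return `ed_state_code()` returns the integer state code(s);
#'   `ed_index()` the 1..4 index into [ED_TYPES].
#' @export
ed_state_code <- function(ed) ed_index(ed) + 1L

#' @rdname ed_state_code
#' @export
ed_index <- function(ed) {
  i <- match(toupper(ed), ED_TYPES)
  if (anyNA(i)) stop("unknown ED type: ", paste(ed[is.na(i)], collapse = ", "))
  i
}

sex_index <- function(sex) {
  if (is.numeric(sex)) {
    if (any(!sex %in% 1:2)) stop("sex index must be 1 (male) or 2 (female)")
    return(as.integer(sex))
  }
  i <- match(tolower(sex), SEXES)
  if (anyNA(i)) stop("unknown sex: ", paste(sex[is.na(i)], collapse = ", "))
  i
}

# resolve an ed filter ("ANY" or specific label) to state codes
ed_filter_codes <- function(ed_filter) {
  if (length(ed_filter) == 1L && toupper(ed_filter) == "ANY") return(ED_STATE_CODES)
  ed_state_code(ed_filter)
}
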