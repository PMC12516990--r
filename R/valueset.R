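#' EQ-5D-3L health states and value sets
#'
#' An EQ-5D-3L health state records a level in {1, 2, 3} on each of five
#' dimensions (mobility, self-care, usual activities, pain/discomfort,
#' anxiety/depression) and is written as a 5-digit code, e.g. "11223".
#' A value set maps each of the 3^5 = 243 states to a utility weight on
#' the scale anchored at 1 = full health.
#'
#' @name eq5d3l
NULL

EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Enumerate all 243 EQ-5D-3L state codes
#'
#' @return character vector of the 243 codes "11111" .. "33333", sorted.
#' @export
eq5d_states <- function() {
  g <- expand.grid(d5 = 1:3, d4 = 1:3, d3 = 1:3, d2 = 1:3, d1 = 1:3)
  sort(paste0(g$d1, g$d2, g$d3, g$d4, g$d5))
}

#' Parse 5-digit state codes into a level matrix
#'
#' @param code character vector of 5-digit codes.
#' @return integer matrix, one row per code, columns the five dimensions.
#' @export
eq5d_parse <- function(code) {
  code <- as.character(code)
  bad <- !grepl("^[123]{5}$", code)
  if (any(bad))
    abort("malformed EQ-5D-3L code(s): %s",
          paste(unique(code[bad]), collapse = ", "))
  m <- matrix(as.integer(unlist(strsplit(code, "", fixed = TRUE))),
              ncol = 5L, byrow = TRUE)
  colnames(m) <- EQ5D_DIMENSIONS
  m
}

#' Build 5-digit codes from dimension levels
#'
#' Inverse of [eq5d_parse()]; rows with any missing level yield `NA`.
#'
#' @param levels integer matrix or data.frame with five columns of levels.
#' @return character vector of codes (NA where any level is missing).
#' @export
eq5d_code <- function(levels) {
  m <- as.matrix(levels)[, seq_len(5L), drop = FALSE]
  if (any(!is.na(m) & !(m %in% 1:3)))
    abort("EQ-5D-3L levels must be 1, 2 or 3")
  out <- apply(m, 1L, function(r) if (anyNA(r)) NA_character_ else
    paste0(r, collapse = ""))
  unname(out)
}

new_value_set <- function(df, name, source = "synthetic") {
  df <- df[order(df$state), c("state", "utility")]
  rownames(df) <- NULL
  structure(df, class = c("cea_value_set", "data.frame"),
            vs_name = name, vs_source = source,
            vs_range = range(df$utility))
}

#' Validate a value set
#'
#' Checks the value-set contract: exactly 243 states, every state present
#' once, full health ("11111") carries the set's maximum weight, all
#' weights at most 1.
#'
#' @param vs a `cea_value_set`.
#' @return `vs`, invisibly, or an error.
#' @export
validate_value_set <- function(vs) {
  if (!inherits(vs, "cea_value_set")) abort("not a value set object")
  if (nrow(vs) != 243L || !identical(sort(vs$state), eq5d_states()))
    abort("value set must map exactly the 243 EQ-5D-3L states")
  if (any(vs$utility > 1 + 1e-12)) abort("utility weights must be <= 1")
  if (abs(vs$utility[vs$state == "11111"] - max(vs$utility)) > 1e-12)
    abort("state 11111 must carry the set's maximum weight")
  invisible(vs)
}

#' Toy closed-form value set
#'
#' Deterministic test set with utility `1 - 0.1 * sum(level - 1)`, so
#' "11111" scores 1 and "33333" scores 0. Used throughout the test suite
#' because every weight has a closed form.
#'
#' @return a `cea_value_set`.
#' @export
toy_value_set <- function() {
  st <- eq5d_states()
  u <- 1 - 0.1 * rowSums(eq5d_parse(st) - 1L)
  validate_value_set(new_value_set(
    data.frame(state = st, utility = round(u, 10)),
    name = "toy_linear", source = "closed form 1 - 0.1*sum(level-1)"))
}

#' Synthetic stand-ins for published EQ-5D-3L value sets
#'
#' The published Swedish experience-based and UK hypothetical value-set
#' coefficients are licensed tables that are not shipped; real analyses
#' load them from user-supplied files via [read_value_set()]. These
#' synthetic stand-ins reproduce only the qualitative features that matter
#' to the pipeline: the experience-based set is compressed near full
#' health (mild states lose little utility), the hypothetical set spreads
#' states more widely and admits states worse than dead (floor -0.594,
#' the conventional worst-state value of the UK tariff scale).
#'
#' @param style `"experience"` (default) or `"hypothetical"`.
#' @return a `cea_value_set`, clearly named `synthetic_*`.
#' @export
synthetic_value_set <- function(style = c("experience", "hypothetical")) {
  style <- match.arg(style)
  st <- eq5d_states()
  lv <- eq5d_parse(st) - 1L            # 0/1/2 decrements
  if (style == "experience") {
    # shallow decrements, convex in level; range roughly [0.34, 0.97]
    dim_w2 <- c(0.07, 0.05, 0.05, 0.09, 0.10)   # level 2 decrement
    dim_w3 <- c(0.17, 0.15, 0.12, 0.24, 0.26)   # level 3 decrement
    u <- 0.97 -
      (lv == 1L) %*% dim_w2 - (lv == 2L) %*% dim_w3
    nm <- "synthetic_experience"
  } else {
    dim_w2 <- c(0.10, 0.10, 0.09, 0.12, 0.12)
    dim_w3 <- c(0.33, 0.26, 0.21, 0.39, 0.34)
    u <- 1 - (rowSums(lv) > 0) * 0.081 -
      (lv == 1L) %*% dim_w2 - (lv == 2L) %*% dim_w3
    u <- pmax(u, -0.594)
    nm <- "synthetic_hypothetical"
  }
  validate_value_set(new_value_set(
    data.frame(state = st, utility = round(as.numeric(u), 10)),
    name = nm, source = "synthetic stand-in, not a published tariff"))
}

#' Look up the utility of an EQ-5D-3L state
#'
#' Pure lookup: the same state under the same value set always returns the
#' same weight, independent of any cohort context.
#'
#' @param state 5-digit code(s), or a 5-column level matrix/data.frame.
#' @param vs a `cea_value_set`.
#' @return numeric utility vector (NA for NA codes).
#' @export
value_state <- function(state, vs) {
  validate_value_set(vs)
  if (is.matrix(state) || is.data.frame(state)) state <- eq5d_code(state)
  state <- as.character(state)
  ok <- !is.na(state)
  if (any(ok & !grepl("^[123]{5}$", state)))
    abort("malformed EQ-5D-3L code(s)")
  idx <- match(state, vs$state)
  if (any(ok & is.na(idx)))
    abort("state absent from value set (malformed value set)")
  vs$utility[idx]
}

#' Read / write a value set file
#'
#' Plain-text format: `#`-prefixed metadata header lines (`name:`,
#' `source:`), then a two-column CSV `state,utility` with 243 rows.
#'
#' @param path file path.
#' @return `read_value_set()` a validated `cea_value_set`;
#'   `write_value_set()` the path, invisibly.
#' @export
read_value_set <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getm <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
    else NA_character_
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        colClasses = c("character", "numeric"))
  names(df) <- c("state", "utility")
  validate_value_set(new_value_set(df,
    name = getm("name") %||% "unnamed",
    source = getm("source") %||% "unknown"))
}

#' @rdname read_value_set
#' @param vs a `cea_value_set` to serialise.
#' @export
write_value_set <- function(vs, path) {
  validate_value_set(vs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name: %s", attr(vs, "vs_name")),
               sprintf("# source: %s", attr(vs, "vs_source")),
               "state,utility",
               sprintf("%s,%.10g", vs$state, vs$utility)), con)
  invisible(path)
}

# nearest-valued state lookup used by the synthetic generator: map a latent
# utility to the state whose weight is closest; ties on distance break to
# the lower weight, ties on weight to the lowest code (fully deterministic)
nearest_state <- function(u, vs) {
  uu <- sort(unique(vs$utility))
  # representative state per unique weight = lowest code
  rep_state <- vapply(uu, function(w)
    min(vs$state[abs(vs$utility - w) < 1e-12]), character(1))
  i <- findInterval(u, uu, all.inside = TRUE)
  hi <- pmin(i + 1L, length(uu))
  pick <- ifelse(abs(u - uu[hi]) < abs(u - uu[i]) - 1e-12, hi, i)
  rep_state[pick]
}
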