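# Landmark and configuration files are YAML: human-readable key/value
# documents with a versioned schema. Unknown fields are rejected rather
# than ignored -- measurement provenance matters clinically.

.LANDMARK_SCHEMA <- "avrot-landmarks-1"
.SIM_SCHEMA <- "avrot-sim-1"

.read_yaml_doc <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .stop_parse(
                    sprintf("%s: not parseable as YAML: %s", path, conditionMessage(e))))
  if (!is.list(doc)) .stop_parse(sprintf("%s: top level must be a mapping", path))
  doc
}

.check_keys <- function(rec, allowed, where) {
  extra <- setdiff(names(rec), allowed)
  if (length(extra))
    .stop_parse(sprintf("%s: unknown field(s) %s (schema rejects unknown fields)",
                        where, paste(sQuote(extra), collapse = ", ")))
}

#' Read a landmark file
#'
#' Reads one YAML landmark document (`schema: avrot-landmarks-1`) holding
#' per-vertebra records `{level, body_quad, pedicle_left_inner,
#' pedicle_right_inner, concave_pedicle_missing, pixel_spacing_mm}`.
#' The optional top-level `frame: y-down` declares an annotation-tool pixel
#' frame; coordinates are then flipped to the package's y-up millimetre
#' convention, and `pixel_spacing_mm` (default 1) converts pixels to
#' millimetres. Records are validated against the landmark-set invariants;
#' violations raise errors naming the offending vertebra.
#'
#' @param path Path to the YAML file.
#' @return A list of [landmark_set()] objects.
#' @export
read_landmarks <- function(path) {
  doc <- .read_yaml_doc(path)
  .check_keys(doc, c("schema", "frame", "vertebrae"), path)
  if (!identical(doc$schema, .LANDMARK_SCHEMA))
    .stop_parse(sprintf("%s: schema must be '%s' (got '%s')",
                        path, .LANDMARK_SCHEMA, doc$schema %||% "<missing>"))
  frame <- doc$frame %||% "y-up"
  if (!frame %in% c("y-up", "y-down"))
    .stop_parse(sprintf("%s: frame must be 'y-up' or 'y-down'", path))
  if (!is.list(doc$vertebrae) || !length(doc$vertebrae))
    .stop_parse(sprintf("%s: 'vertebrae' must be a non-empty list", path))

  lapply(seq_along(doc$vertebrae), function(i) {
    rec <- doc$vertebrae[[i]]
    where <- sprintf("%s: vertebra record %d (%s)", path, i,
                     rec$level %||% "level missing")
    .check_keys(rec, c("level", "body_quad", "pedicle_left_inner",
                       "pedicle_right_inner", "concave_pedicle_missing",
                       "pixel_spacing_mm"), where)
    if (is.null(rec$level) || is.null(rec$body_quad))
      .stop_parse(paste0(where, ": 'level' and 'body_quad' are required"))
    spacing <- rec$pixel_spacing_mm %||% 1
    if (!is.numeric(spacing) || spacing <= 0)
      .stop_parse(paste0(where, ": pixel_spacing_mm must be positive"))
    conv <- function(p) {
      if (is.null(p)) return(NULL)
      p <- .as_point(p) * spacing
      if (frame == "y-down") p[2] <- -p[2]
      p
    }
    quad <- tryCatch(.as_quad(rec$body_quad),
                     error = function(e) .stop_parse(
                       paste0(where, ": ", conditionMessage(e))))
    quad <- quad * spacing
    if (frame == "y-down") quad[, 2] <- -quad[, 2]
    tryCatch(
      landmark_set(rec$level, quad,
                   pedicle_left_inner = conv(rec$pedicle_left_inner),
                   pedicle_right_inner = conv(rec$pedicle_right_inner),
                   concave_pedicle_missing = rec$concave_pedicle_missing %||% "none"),
      error = function(e) .stop_validation(
        paste0(where, ": ", conditionMessage(e))))
  })
}

#' Write landmark sets to a YAML landmark file
#'
#' Emits the y-up millimetre frame (`pixel_spacing_mm: 1`), so
#' `read_landmarks(write_landmarks(x, path))` is the identity on values.
#'
#' @param x A [landmark_set()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path) {
  if (inherits(x, "landmark_set")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "landmark_set")))
  recs <- lapply(x, function(lm) {
    pt <- function(p) if (anyNA(p)) NULL else as.list(as.numeric(p))
    rec <- list(level = lm$level,
                body_quad = lapply(seq_len(4), function(i) as.list(as.numeric(lm$body_quad[i, ]))),
                pedicle_left_inner = pt(lm$pedicle_left_inner),
                pedicle_right_inner = pt(lm$pedicle_right_inner),
                concave_pedicle_missing = lm$concave_pedicle_missing,
                pixel_spacing_mm = 1)
    rec[!vapply(rec, is.null, logical(1))]
  })
  doc <- list(schema = .LANDMARK_SCHEMA, frame = "y-up", vertebrae = recs)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a simulation configuration file
#'
#' YAML document (`schema: avrot-sim-1`) describing a rotation-device
#' experiment: the vertebra model (level plus optional dimension
#' overrides), the angle list, the number of raters, the landmark noise SD
#' and the seed.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `model` (a [vertebra_model()]) and
#'   `params` (arguments for [generate_series()]).
#' @export
read_sim_config <- function(path) {
  doc <- .read_yaml_doc(path)
  allowed <- c("schema", "level", "z_mm", "width_mm", "x_mm", "x_over_z",
               "pedicle_gap_mm", "wedge_deg", "criterion_exact", "alphas",
               "n_raters", "noise_sd_mm", "seed", "forward_model",
               "visibility_limit_deg", "drop_hidden")
  .check_keys(doc, allowed, path)
  if (!identical(doc$schema, .SIM_SCHEMA))
    .stop_parse(sprintf("%s: schema must be '%s'", path, .SIM_SCHEMA))
  if (is.null(doc$level)) .stop_parse(sprintf("%s: 'level' is required", path))

  model <- tryCatch({
    if (isTRUE(doc$criterion_exact)) {
      criterion_phantom(doc$level, z_mm = doc$z_mm, width_mm = doc$width_mm,
                        pedicle_gap_mm = doc$pedicle_gap_mm,
                        wedge_deg = doc$wedge_deg %||% 0)
    } else {
      m <- vertebra_model(doc$level, z_mm = doc$z_mm, width_mm = doc$width_mm,
                          x_mm = doc$x_mm, pedicle_gap_mm = doc$pedicle_gap_mm,
                          wedge_deg = doc$wedge_deg %||% 0)
      if (!is.null(doc$x_over_z)) m$x_mm <- doc$x_over_z * m$z_mm
      m
    }
  }, avrot_error = function(e) .stop_validation(
    sprintf("%s: %s", path, conditionMessage(e))))

  params <- list(alphas = as.numeric(doc$alphas %||% seq(0, 45, by = 3)),
                 n_raters = doc$n_raters %||% 1L,
                 noise_sd_mm = doc$noise_sd_mm %||% 0,
                 seed = doc$seed %||% 1L,
                 forward_model = doc$forward_model %||% "tan",
                 visibility_limit_deg = doc$visibility_limit_deg %||% 30,
                 drop_hidden = isTRUE(doc$drop_hidden))
  list(model = model, params = params)
}

#' Results table for a set of measurements
#'
#' @param measurements A list of `rotation_measurement` objects.
#' @return Data frame with one row per vertebra: vertebra, rule,
#'   alpha_deg, d_mm, z_mm and flags.
#' @export
results_table <- function(measurements) {
  if (inherits(measurements, "rotation_measurement"))
    measurements <- list(measurements)
  do.call(rbind, lapply(measurements, as.data.frame))
}

# Delimited table with provenance header lines (tool version, config hash,
# seed); rerunning the same config reproduces the file byte for byte.
.write_table_with_header <- function(df, path, config_hash = NA, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# avrot %s", as.character(utils::packageVersion("avrot"))),
               sprintf("# config_hash: %s", config_hash),
               sprintf("# seed: %s", seed)), con)
  utils::write.table(format(df, trim = TRUE, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.config_hash <- function(path) unname(tools::md5sum(path))
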