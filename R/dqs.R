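# Diet quality score (DQS): a 5-15 summary of food-frequency questionnaire
# responses, computed as the sum of five component scores in {1, 2, 3}.
# The component-to-item map and the frequency cutpoints ship as a
# documented, serializable configuration because FFQ instruments differ.

#' Default DQS scoring configuration
#'
#' Maps the 20 default FFQ items (1-8 frequency categories) onto five diet
#' components of four items each. "Healthy" components score higher when
#' eaten more often, "unhealthy" components when eaten less often. Each
#' component's score is 1, 2 or 3 depending on where the mean item
#' frequency falls relative to the two cutpoints, and the DQS is the sum
#' of the five component scores, giving the 5-15 range (higher =
#' healthier diet).
#'
#' @param n_items Total number of FFQ items (must be divisible by the five
#'   components; default 20).
#' @return A list of class `uti_dqs_config` with one entry per component:
#'   `items` (1-based FFQ indices), `direction` (`"healthy"` /
#'   `"unhealthy"`), `cutpoints` (length 2, increasing).
#' @export
dqs_default_config <- function(n_items = 20) {
  if (n_items %% 5 != 0) {
    stop("the default configuration splits the FFQ into 5 equal components",
         call. = FALSE)
  }
  per <- n_items / 5
  blocks <- split(seq_len(n_items), rep(1:5, each = per))
  structure(
    list(
      vegetables = list(items = blocks[[1]], direction = "healthy",
                        cutpoints = c(3, 5)),
      fruit = list(items = blocks[[2]], direction = "healthy",
                   cutpoints = c(3, 5)),
      sugary_foods = list(items = blocks[[3]], direction = "unhealthy",
                          cutpoints = c(3, 5)),
      processed_meat = list(items = blocks[[4]], direction = "unhealthy",
                            cutpoints = c(3, 5)),
      wholegrains_fish = list(items = blocks[[5]], direction = "healthy",
                              cutpoints = c(3, 5))
    ),
    class = "uti_dqs_config"
  )
}

check_dqs_config <- function(config, n_items) {
  items <- unlist(lapply(config, `[[`, "items"))
  if (anyDuplicated(items)) {
    stop("DQS configuration error: an FFQ item is mapped to two components",
         call. = FALSE)
  }
  if (!setequal(items, seq_len(n_items))) {
    stop(sprintf(
      "DQS configuration error: components cover items {%s} but the FFQ has %d items",
      paste(sort(items), collapse = ","), n_items), call. = FALSE)
  }
  for (comp in config) {
    if (!comp$direction %in% c("healthy", "unhealthy")) {
      stop("DQS configuration error: direction must be 'healthy' or 'unhealthy'",
           call. = FALSE)
    }
    if (length(comp$cutpoints) != 2 || diff(comp$cutpoints) <= 0) {
      stop("DQS configuration error: cutpoints must be two increasing values",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Component score in {1,2,3} from a mean frequency.
dqs_component_score <- function(mu, direction, cutpoints) {
  healthy_score <- if (mu < cutpoints[1]) 1L else if (mu < cutpoints[2]) 2L else 3L
  if (direction == "healthy") healthy_score else 4L - healthy_score
}

#' Score the diet quality score (DQS)
#'
#' Sums the five component scores derived from the FFQ responses under a
#' scoring configuration. With the default five-component configuration
#' the score ranges 5-15, higher meaning a healthier reported diet.
#'
#' @param ffq Numeric vector of FFQ responses in 1-8, one per item.
#' @param config Scoring configuration, see [dqs_default_config()].
#' @return Integer DQS.
#' @export
score_dqs <- function(ffq, config = dqs_default_config(length(ffq))) {
  ffq <- as.numeric(ffq)
  if (any(is.na(ffq)) || any(ffq < 1 | ffq > 8)) {
    stop("FFQ responses must lie in [1, 8] with no missing values",
         call. = FALSE)
  }
  check_dqs_config(config, length(ffq))
  sum(vapply(config, function(comp) {
    dqs_component_score(mean(ffq[comp$items]), comp$direction,
                        comp$cutpoints)
  }, integer(1)))
}

#' Read / write a DQS scoring configuration
#'
#' The configuration serializes to JSON (or YAML when the file extension
#' is `.yaml`/`.yml` and the \pkg{yaml} package is available), so the
#' component-to-item map and cutpoints can be audited and swapped per
#' instrument.
#'
#' @param config A `uti_dqs_config` list.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_dqs_config()` returns `path` invisibly;
#'   `read_dqs_config()` returns the configuration.
#' @name dqs_config_io
NULL

#' @rdname dqs_config_io
#' @export
write_dqs_config <- function(config, path) {
  plain <- lapply(config, function(comp) {
    list(items = as.integer(comp$items), direction = comp$direction,
         cutpoints = as.numeric(comp$cutpoints))
  })
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed for YAML output", call. = FALSE)
    }
    writeLines(yaml::as.yaml(plain), path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname dqs_config_io
#' @export
read_dqs_config <- function(path) {
  plain <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed for YAML input", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  structure(
    lapply(plain, function(comp) {
      list(items = as.integer(unlist(comp$items)),
           direction = as.character(unlist(comp$direction)),
           cutpoints = as.numeric(unlist(comp$cutpoints)))
    }),
    class = "uti_dqs_config"
  )
}
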