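.norm_label <- function(x) tolower(trimws(x))

#' Load the group taxonomy
#'
#' The taxonomy maps working-activity strings onto six mutually exclusive
#' activity groups (1 surface treatment, 2 high temperature processing,
#' 3 filling/transport/storage, 4 machining/abrasive techniques, 5 forming,
#' 6 others), material subcategories onto three pooled material groups
#' (A mineral-, B metal-, C fiber-dominated), and selected activity subsets
#' onto the heuristic groups alpha-eta (soldering, casting, welding, high
#' temperature cutting, blasting, chiseling/embossing, wire drawing). It
#' ships as an editable YAML file so the activity lists can be extended to
#' local coding systems.
#'
#' @param path Path to a taxonomy YAML file; defaults to the file shipped
#'   with the package.
#' @return An object of class `dust_taxonomy`.
#' @export
load_taxonomy <- function(path = system.file("extdata", "taxonomy.yaml",
                                             package = "dustconv")) {
  if (!nzchar(path) || !file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (field in c("activity_groups", "material_groups", "heuristic_groups",
                  "combined_groups")) {
    if (is.null(raw[[field]])) stop("taxonomy missing field: ", field)
  }

  activity_map <- character()
  for (gid in names(raw$activity_groups)) {
    acts <- .norm_label(unlist(raw$activity_groups[[gid]]$activities))
    if (any(acts %in% names(activity_map))) {
      dup <- intersect(acts, names(activity_map))
      stop("activity assigned to two groups: ", paste(dup, collapse = ", "))
    }
    activity_map[acts] <- gid
  }

  material_map <- character()
  for (gid in names(raw$material_groups)) {
    subs <- vapply(raw$material_groups[[gid]]$subcategories,
                   function(s) .norm_label(s$code), character(1))
    material_map[subs] <- gid
  }

  heuristics <- lapply(raw$heuristic_groups, function(h) {
    list(name = h$name, originating_group = as.character(h$originating_group),
         material = h$material, activities = .norm_label(unlist(h$activities)))
  })
  # heuristic activities must belong to the activity group they originate from
  for (hid in names(heuristics)) {
    h <- heuristics[[hid]]
    origin_act <- sub("-.*$", "", h$originating_group)
    mapped <- unname(activity_map[h$activities])
    wrong <- h$activities[is.na(mapped) | mapped != origin_act]
    if (length(wrong)) {
      stop("heuristic group ", hid, " lists activities outside its ",
           "originating activity group: ", paste(wrong, collapse = ", "))
    }
  }

  structure(
    list(
      activity_map = activity_map,
      material_map = material_map,
      activity_names = vapply(raw$activity_groups, `[[`, character(1), "name"),
      material_names = vapply(raw$material_groups, `[[`, character(1), "name"),
      heuristics = heuristics,
      combined_groups = unlist(raw$combined_groups)
    ),
    class = "dust_taxonomy"
  )
}

#' @export
print.dust_taxonomy <- function(x, ...) {
  cat("Dust group taxonomy\n")
  cat(sprintf("  activity groups:  %d (%d activity strings)\n",
              length(x$activity_names), length(x$activity_map)))
  cat(sprintf("  material groups:  %d (%d subcategories)\n",
              length(x$material_names), length(x$material_map)))
  cat(sprintf("  combined groups:  %s\n", paste(x$combined_groups, collapse = ", ")))
  cat(sprintf("  heuristic groups: %s\n", paste(names(x$heuristics), collapse = ", ")))
  invisible(x)
}

#' Assign measurement pairs to taxonomy groups
#'
#' Adds four columns to a pair data frame:
#' * `activity_group`: "1".."6"; unknown activity strings fall back to "6",
#' * `material_group`: "A", "B", "C" or "unclassified",
#' * `combined_group`: one of "1-A", "2-B", "4-A", "6-B", else `NA`,
#' * `heuristic_group`: "alpha".."eta" when the activity is on a heuristic
#'   list and the material requirement is met, else `NA`.
#'
#' The assignment is deterministic; an unclassified material never yields a
#' combined or heuristic group.
#'
#' @param pairs Pair data frame with `working_activity` and
#'   `material_category` columns.
#' @param taxonomy A `dust_taxonomy` from [load_taxonomy()].
#' @return `pairs` with the four group columns appended.
#' @export
assign_groups <- function(pairs, taxonomy) {
  stopifnot(inherits(taxonomy, "dust_taxonomy"))
  act <- .norm_label(pairs$working_activity)
  mat <- .norm_label(pairs$material_category)

  activity <- unname(taxonomy$activity_map[act])
  activity[is.na(activity)] <- "6"
  material <- unname(taxonomy$material_map[mat])
  material[is.na(material)] <- "unclassified"

  combined <- paste0(activity, "-", material)
  combined[!(combined %in% taxonomy$combined_groups) |
             material == "unclassified"] <- NA_character_

  heuristic <- rep(NA_character_, nrow(pairs))
  for (hid in names(taxonomy$heuristics)) {
    h <- taxonomy$heuristics[[hid]]
    need <- switch(h$material,
                   metal = material == "B",
                   mineral = material == "A",
                   all = material %in% c("A", "B", "C"),
                   stop("unknown material requirement: ", h$material))
    hit <- (act %in% h$activities) & need & is.na(heuristic)
    heuristic[hit] <- hid
  }

  pairs$activity_group <- activity
  pairs$material_group <- material
  pairs$combined_group <- combined
  pairs$heuristic_group <- heuristic
  pairs
}

#' Resolve the conversion group to use for a pair
#'
#' Walks the group hierarchy from most to least specific: heuristic group,
#' then combined group, then working-activity group, then material group.
#' Activity group 6 ("others") is the fallback bucket for unknown activity
#' codes and is treated as uninformative at the activity level, so a pair
#' with activity 6 resolves through its material group. When nothing
#' resolves, the whole-dataset function ("0") is returned only if
#' `allow_whole_dataset = TRUE` (with a warning — grouped functions should
#' always be preferred over the whole-dataset fit); otherwise this is an
#' error.
#'
#' Adding information is monotone: a pair that gains a heuristic label never
#' resolves to a less specific group.
#'
#' @param assignment Data frame with columns `activity_group`,
#'   `material_group`, `combined_group`, `heuristic_group` (one or more
#'   rows), as produced by [assign_groups()].
#' @param allow_whole_dataset Permit falling back to the whole-dataset
#'   conversion function ("0").
#' @return Character vector of group ids, one per row.
#' @export
resolve_conversion_group <- function(assignment, allow_whole_dataset = FALSE) {
  required <- c("activity_group", "material_group", "combined_group",
                "heuristic_group")
  missing <- setdiff(required, names(assignment))
  if (length(missing)) {
    stop("assignment lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- assignment$heuristic_group
  out[is.na(out)] <- assignment$combined_group[is.na(out)]
  use_act <- is.na(out) & assignment$activity_group != "6"
  out[use_act] <- assignment$activity_group[use_act]
  use_mat <- is.na(out) & assignment$material_group != "unclassified"
  out[use_mat] <- assignment$material_group[use_mat]
  if (anyNA(out)) {
    if (!allow_whole_dataset) {
      stop("no applicable group for ", sum(is.na(out)), " pair(s); ",
           "set allow_whole_dataset = TRUE to fall back to the ",
           "whole-dataset conversion function")
    }
    warning("falling back to the whole-dataset conversion function for ",
            sum(is.na(out)), " pair(s); grouped functions are preferred")
    out[is.na(out)] <- "0"
  }
  out
}

#' Split pairs by group at one taxonomy level
#'
#' At the `activity` level the result is a partition of all pairs; at the
#' `material` level "unclassified" forms its own bin; at the `combined` and
#' `heuristic` levels pairs without an assignment are dropped.
#'
#' @param pairs Pair data frame with group columns (see [assign_groups()]).
#' @param level One of `"activity"`, `"material"`, `"combined"`,
#'   `"heuristic"`.
#' @return Named list of pair data frames.
#' @export
split_by_group <- function(pairs,
                           level = c("activity", "material", "combined",
                                     "heuristic")) {
  level <- match.arg(level)
  col <- paste0(level, "_group")
  if (!col %in% names(pairs)) {
    stop("pairs have no ", col, " column; run assign_groups() first")
  }
  g <- pairs[[col]]
  keep <- !is.na(g)
  split(pairs[keep, , drop = FALSE], g[keep])
}
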