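.safbdg_flags <- c("fruit_veg", "legume", "dairy_liquid", "hard_cheese",
                   "fish_chicken_leanmeat", "egg", "starchy")
.fao_groups <- c(
  "cereals, roots and tubers",        # 1
  "meat, poultry and fish",           # 2
  "dairy",                            # 3
  "eggs",                             # 4
  "vitamin A-rich vegetables and fruit", # 5
  "legumes",                          # 6
  "other vegetables",                 # 7
  "other fruits",                     # 8
  "fats and oils"                     # 9
)

#' Construct a food-group mapping
#'
#' A mapping assigns every food item to at most one scored SAFBDG food group
#' (the seven flags below are mutually exclusive) and to one of the nine FAO
#' dietary-diversity groups, and carries the grams-per-unit weight for starchy
#' items (one food-guide unit, e.g. 125 g soft maize-meal porridge, 35 g
#' bread, 65 g cooked rice).
#'
#' @param items data.frame with columns `item_id`, `dds_group` (integer 1-9 or
#'   NA for unscored items), `group` (one of `"fruit_veg"`, `"legume"`,
#'   `"dairy_liquid"`, `"hard_cheese"`, `"fish_chicken_leanmeat"`, `"egg"`,
#'   `"starchy"`, or `"none"`), `starchy_unit_g` (grams per starchy unit; NA
#'   unless `group == "starchy"`), and optionally `kj_per_100g`.
#' @param schema_version integer config schema version.
#' @return An object of class `group_mapping`.
#' @export
group_mapping <- function(items, schema_version = 1L) {
  stopifnot(is.data.frame(items),
            all(c("item_id", "dds_group", "group") %in% names(items)))
  items$item_id <- as.character(items$item_id)
  if (anyDuplicated(items$item_id)) {
    stop("duplicated item_id in mapping", call. = FALSE)
  }
  ok <- is.na(items$dds_group) | items$dds_group %in% 1:9
  if (!all(ok)) {
    stop("dds_group must be one of the nine FAO groups (1-9) or NA; bad: ",
         paste(items$item_id[!ok], collapse = ", "), call. = FALSE)
  }
  bad_grp <- !items$group %in% c(.safbdg_flags, "none")
  if (any(bad_grp)) {
    stop("unknown SAFBDG group for item(s): ",
         paste(items$item_id[bad_grp], collapse = ", "), call. = FALSE)
  }
  if (!"starchy_unit_g" %in% names(items)) items$starchy_unit_g <- NA_real_
  if (!"kj_per_100g" %in% names(items)) items$kj_per_100g <- NA_real_
  st <- items$group == "starchy"
  if (any(st & (is.na(items$starchy_unit_g) | items$starchy_unit_g <= 0))) {
    stop("config error: starchy item(s) lack a positive starchy_unit_g: ",
         paste(items$item_id[st & (is.na(items$starchy_unit_g) |
                                     items$starchy_unit_g <= 0)],
               collapse = ", "), call. = FALSE)
  }
  structure(list(items = items, schema_version = as.integer(schema_version)),
            class = "group_mapping")
}

#' @export
print.group_mapping <- function(x, ...) {
  cat(sprintf("SAFBDG food-group mapping: %d items (schema v%d)\n",
              nrow(x$items), x$schema_version))
  print(table(x$items$group))
  invisible(x)
}

#' Read a food-group mapping from a YAML config
#'
#' The config must carry `schema_version` and a list `items`, each entry with
#' `item_id`, `dds_group` (1-9 or absent), a `flags` list naming at most one
#' scored SAFBDG group, and `starchy_unit_g` for starchy items. An item
#' flagged with two SAFBDG groups (e.g. egg and dairy) is rejected as
#' ambiguous: the adherence rules treat those groups as disjoint.
#'
#' @param config_path YAML path.
#' @return A [group_mapping()].
#' @export
read_mapping <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$schema_version)) {
    stop("mapping config lacks schema_version", call. = FALSE)
  }
  rows <- lapply(cfg$items, function(it) {
    flags <- unlist(it$flags)
    flags <- flags[flags %in% .safbdg_flags]
    if (length(flags) > 1) {
      stop("ambiguous mapping for item '", it$item_id,
           "': SAFBDG flags are mutually exclusive (",
           paste(flags, collapse = " + "), ")", call. = FALSE)
    }
    data.frame(
      item_id = it$item_id,
      dds_group = if (is.null(it$dds_group)) NA_integer_ else
        as.integer(it$dds_group),
      group = if (length(flags)) flags else "none",
      starchy_unit_g = if (is.null(it$starchy_unit_g)) NA_real_ else
        as.numeric(it$starchy_unit_g),
      kj_per_100g = if (is.null(it$kj_per_100g)) NA_real_ else
        as.numeric(it$kj_per_100g),
      stringsAsFactors = FALSE
    )
  })
  group_mapping(do.call(rbind, rows),
                schema_version = cfg$schema_version)
}

#' Write a mapping to YAML
#'
#' Emits the schema [read_mapping()] consumes.
#'
#' @param mapping a `group_mapping`.
#' @param path output YAML path.
#' @export
write_mapping <- function(mapping, path) {
  items <- lapply(seq_len(nrow(mapping$items)), function(i) {
    r <- mapping$items[i, ]
    it <- list(item_id = r$item_id)
    if (!is.na(r$dds_group)) it$dds_group <- as.integer(r$dds_group)
    it$flags <- if (r$group == "none") list() else list(r$group)
    if (!is.na(r$starchy_unit_g)) it$starchy_unit_g <- r$starchy_unit_g
    if (!is.na(r$kj_per_100g)) it$kj_per_100g <- r$kj_per_100g
    it
  })
  yaml::write_yaml(list(schema_version = mapping$schema_version,
                        items = items), path)
  invisible(path)
}

# Items present in the intake table but absent from the mapping.
check_mapping_coverage <- function(mapping, intake_items, action = "warn") {
  unmapped <- setdiff(intake_items, mapping$items$item_id)
  if (length(unmapped)) {
    msg <- paste0("intake item(s) not covered by the mapping: ",
                  paste(unmapped, collapse = ", "))
    if (action == "error") stop(msg, call. = FALSE) else warning(msg,
                                                                 call. = FALSE)
  }
  invisible(unmapped)
}
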