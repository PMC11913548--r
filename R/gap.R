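# Protected-area gap analysis: precedence resolution among protection
# categories, rasterization to the analysis grid, and tabulation of
# habitat proportions and areas per category.

category_precedence <- c("Proclamation", "Designated", "Other", "BLM")

points_in_polygon <- function(x, y, geometry) {
  sp::point.in.polygon(x, y, geometry[, 1], geometry[, 2]) > 0
}

#' Resolve protection-category precedence and rasterize
#'
#' Applies the bookkeeping rules of the protected-areas database prep:
#' tribal and Department of Defense lands are removed; state- and NGO-owned
#' Fee parcels are merged into the Proclamation category; Designated areas
#' contained within Proclamation areas are counted as Proclamation (so no
#' area is counted twice), and likewise each cell takes the highest-
#' precedence category covering it (Proclamation > Designated > Other >
#' BLM). Solar-development zones are rasterized separately as an overlay
#' (they may overlap BLM). Rasterization assigns a polygon to every cell
#' whose center it contains.
#'
#' @param polys A `gs_polygons` tibble with a `category` column (and
#'   optionally `owner` for Fee parcels).
#' @param grid The analysis `gs_grid`.
#' @return A `gs_protection`: `category` (`gs_raster` of codes, 0 = none),
#'   `categories` (code labels), `solar` (0/1 `gs_raster`), `polygons`
#'   (the resolved polygon table).
#' @export
resolve_precedence <- function(polys, grid) {
  polys <- tibble::as_tibble(polys)
  polys <- dplyr::filter(polys, !.data$category %in% c("Tribal", "DoD"))
  if ("owner" %in% names(polys)) {
    is_fee <- polys$category == "Fee"
    eligible <- is_fee & polys$owner %in% c("state", "ngo")
    polys$category[eligible] <- "Proclamation"
    polys <- polys[!(is_fee & !eligible), , drop = FALSE]
  } else {
    polys <- dplyr::filter(polys, .data$category != "Fee")
  }
  cc <- cell_centers(grid)
  code <- matrix(0L, grid$n_rows, grid$n_cols)
  # paint from lowest to highest precedence so the highest wins
  for (ci in rev(seq_along(category_precedence))) {
    cat_nm <- category_precedence[ci]
    for (i in which(polys$category == cat_nm)) {
      inside <- points_in_polygon(cc$x, cc$y, polys$geometry[[i]])
      code[matrix(inside, grid$n_rows, grid$n_cols)] <- ci
    }
  }
  solar <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (i in which(polys$category == "Solar")) {
    inside <- points_in_polygon(cc$x, cc$y, polys$geometry[[i]])
    solar <- solar | matrix(inside, grid$n_rows, grid$n_cols)
  }
  structure(list(category = raster_layer(grid, code, "protection"),
                 categories = category_precedence,
                 solar = raster_layer(grid, solar + 0, "solar"),
                 polygons = polys),
            class = "gs_protection")
}

#' Tabulate habitat over protection categories
#'
#' For a binary habitat mask: the proportion and area (hectares) of habitat
#' cells in each mutually exclusive category, plus the derived rows Total
#' protected (Proclamation + Designated + Other), Total public (protected +
#' BLM), the Solar overlay (tabulated independently since it may overlap
#' BLM), and the uncategorized remainder (which restores the exclusive
#' proportions to exactly one).
#'
#' @param habitat_mask A 0/1 `gs_raster`.
#' @param protection A `gs_protection`.
#' @return Tibble with `category`, `proportion`, `hectares`. An empty
#'   habitat mask yields `NA` proportions and `attr(, "empty") = TRUE`.
#' @export
tabulate_gap <- function(habitat_mask, protection) {
  g <- habitat_mask$grid
  stop_if_grid_mismatch(g, protection$category$grid, "protection raster")
  hab <- !is.na(habitat_mask$values) & habitat_mask$values > 0
  n_hab <- sum(hab)
  ha <- g$cell_size^2 / 1e4
  code <- protection$category$values
  cats <- protection$categories
  counts <- vapply(seq_along(cats), function(ci) sum(hab & code == ci),
                   numeric(1))
  names(counts) <- cats
  protected <- sum(counts[c("Proclamation", "Designated", "Other")])
  public <- protected + counts[["BLM"]]
  solar <- sum(hab & protection$solar$values > 0)
  remainder <- n_hab - sum(counts)
  rows <- c(counts, `Total protected` = protected, `Total public` = public,
            Solar = solar, Unprotected = remainder)
  out <- tibble::tibble(
    category = names(rows),
    proportion = if (n_hab > 0) as.numeric(rows) / n_hab else NA_real_,
    hectares = as.numeric(rows) * ha)
  if (n_hab == 0) attr(out, "empty") <- TRUE
  out
}
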