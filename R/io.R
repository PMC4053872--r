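#' Read and write the standard CSV interchange formats
#'
#' Panels: `district,year,population,admissions`. District info:
#' `district,x,y,hospitals`. Case points: `district,year,x,y`.
#'
#' @param path File path.
#' @name citysurv-io
NULL

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_domain(path, " lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname citysurv-io
#' @export
read_panel_csv <- function(path) {
  read_csv_checked(path, c("district", "year", "population", "admissions"))
}

#' @rdname citysurv-io
#' @export
read_district_info_csv <- function(path) {
  read_csv_checked(path, c("district", "x", "y", "hospitals"))
}

#' @rdname citysurv-io
#' @export
read_case_points_csv <- function(path) {
  read_csv_checked(path, c("district", "year", "x", "y"))
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write case points as a GeoJSON FeatureCollection of Points
#'
#' @param points data.frame `district, year, x, y`.
#' @param path Output file.
#' @export
write_points_geojson <- function(points, path) {
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = list(district = points$district[i],
                           year = points$year[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write annual ellipses as GeoJSON polygons
#'
#' Each ellipse is discretized as a closed 64-gon.
#'
#' @param ellipses An [annual_ellipses()] table.
#' @param path Output file.
#' @export
write_ellipses_geojson <- function(ellipses, path) {
  features <- lapply(seq_len(nrow(ellipses)), function(i) {
    e <- structure(list(center = list(x = ellipses$cx[i], y = ellipses$cy[i]),
                        sde_x = ellipses$sde_x[i], sde_y = ellipses$sde_y[i],
                        theta = ellipses$theta_deg[i]),
                   class = "sd_ellipse")
    poly <- ellipse_polygon(e, 64L)
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(poly)),
                                                   function(j) unname(poly[j, ])))),
         properties = list(year = ellipses$year[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
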