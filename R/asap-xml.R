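#' Write polygon annotations as ASAP-dialect XML
#'
#' Writes lesion or detection outlines in the XML dialect of the open
#' Automated Slide Analysis Platform, the interchange format used for
#' ground-truth and reviewable prediction annotations. Coordinates are slide
#' micrometers, origin top-left, x right, y down.
#'
#' @param polygons List of two-column (x, y) vertex matrices; a closing
#'   vertex equal to the first is dropped on write.
#' @param path Output file.
#' @param names Optional annotation names (default `Annotation 0`, ...).
#' @param group Group name recorded for every annotation.
#' @return `path`, invisibly.
#' @export
write_asap_xml <- function(polygons, path, names = NULL, group = "None") {
  doc <- xml2::xml_new_root("ASAP_Annotations")
  anns <- xml2::xml_add_child(doc, "Annotations")
  if (is.null(names)) {
    names <- sprintf("Annotation %d", seq_along(polygons) - 1L)
  }
  for (k in seq_along(polygons)) {
    poly <- polygons[[k]]
    n <- nrow(poly)
    if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
    ann <- xml2::xml_add_child(
      anns, "Annotation", Name = names[k], Type = "Polygon",
      PartOfGroup = group, Color = "#F4FA58")
    coords <- xml2::xml_add_child(ann, "Coordinates")
    for (j in seq_len(nrow(poly))) {
      xml2::xml_add_child(coords, "Coordinate", Order = as.character(j - 1L),
                          X = sprintf("%.6f", poly[j, 1]),
                          Y = sprintf("%.6f", poly[j, 2]))
    }
  }
  xml2::xml_add_child(doc, "AnnotationGroups")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read ASAP-dialect annotation XML
#'
#' @param path Annotation XML file.
#' @return A tibble with `name`, `group`, and a `polygon` list-column of
#'   two-column (x, y) vertex matrices in micrometers.
#' @export
read_asap_xml <- function(path) {
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  polys <- lapply(anns, function(a) {
    co <- xml2::xml_find_all(a, ".//Coordinate")
    ord <- as.integer(xml2::xml_attr(co, "Order"))
    m <- cbind(x = as.numeric(xml2::xml_attr(co, "X")),
               y = as.numeric(xml2::xml_attr(co, "Y")))
    m[order(ord), , drop = FALSE]
  })
  tibble::tibble(
    name = xml2::xml_attr(anns, "Name"),
    group = xml2::xml_attr(anns, "PartOfGroup"),
    polygon = polys
  )
}
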