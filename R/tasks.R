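# Protocol metadata: object classes and functional task categories.

vm_object_classes <- c(
  "bottle", "door handle", "can", "mug", "key", "pencilcase", "plate",
  "book", "drawer", "ball", "bulb", "jar", "clothespin", "remote",
  "knife", "fork", "screwdriver", "wrench"
)

vm_task_table <- data.frame(
  grasp = c("medium wrap", "medium wrap", "lateral", "lateral",
            "parallel extension", "parallel extension", "tripod grasp",
            "tripod grasp", "power sphere", "power sphere",
            "precision disk", "precision disk", "prismatic pinch",
            "prismatic pinch", "index finger extension",
            "index finger extension", "adducted thumb", "adducted thumb",
            "prismatic four finger", "prismatic four finger"),
  instruction = c(
    "Drink from the can",
    "Open and close the door handle",
    "Turn the key in the lock",
    "Open and close the pencil case",
    "Lift the plate",
    "Lift the book",
    "Open and close the cap of the bottle",
    "Open and close the drawer",
    "Move the ball to the right and back",
    "Move the keys forwards and backwards",
    "Open and close the lid of jar",
    "Screw and unscrew the light bulb",
    "Squeeze the clothespin",
    "Move the keys forwards and backwards",
    "Press a button on the remote control",
    "Cut bread with the knife",
    "Turn the screwdriver",
    "Move the wrench to the right and back",
    "Move the knife forwards and backwards",
    "Move the fork to the right and back"
  ),
  object = c("can", "door handle", "key", "pencilcase", "plate", "book",
             "bottle", "drawer", "ball", "key", "jar", "bulb",
             "clothespin", "key", "remote", "knife", "screwdriver",
             "wrench", "knife", "fork"),
  position = c("standing", "standing", "standing", "standing", "standing",
               "standing", "standing", "standing", "standing", "standing",
               "seated", "seated", "seated", "seated", "seated", "seated",
               "seated", "seated", "seated", "seated"),
  category = c("lifting", "in place", "in place", "in place", "lifting",
               "lifting", "in place", "in place", "displacement",
               "displacement", "in place", "in place", "in place",
               "displacement", "in place", "in place", "in place",
               "displacement", "displacement", "displacement"),
  stringsAsFactors = FALSE
)

#' Task metadata tables
#'
#' `task_categories()` returns the functional-task table (grasp type, vocal
#' instruction, target object class, execution position and visual-behavior
#' category); `object_classes()` the 18 object class labels used for the
#' target instances.
#'
#' @return A data frame, respectively a character vector.
#' @export
task_categories <- function() vm_task_table

#' @rdname task_categories
#' @export
object_classes <- function() vm_object_classes

#' Assign the visual-behavior category of a trial
#'
#' Functional tasks are grouped into three categories by the kind of
#' manipulation they require: `"in place"` (the object does not leave its
#' position), `"lifting"` and `"displacement"`. Static grasp trials are
#' labelled `"static"`.
#'
#' @param instruction character vector of vocal instructions (ignored for
#'   static trials).
#' @param task_type `"static"` or `"functional"`, recycled as needed.
#' @return Character vector of categories; unknown functional instructions
#'   yield `NA` with a warning.
#' @examples
#' category_assign("Drink from the can")            # "lifting"
#' category_assign("Squeeze the clothespin")        # "in place"
#' category_assign("anything", task_type = "static")
#' @export
category_assign <- function(instruction, task_type = "functional") {
  n <- max(length(instruction), length(task_type))
  instruction <- rep_len(as.character(instruction), n)
  task_type <- rep_len(task_type, n)
  norm <- function(x) tolower(trimws(gsub("[*]", "", x)))
  idx <- match(norm(instruction), norm(vm_task_table$instruction))
  out <- vm_task_table$category[idx]
  out[task_type == "static"] <- "static"
  if (anyNA(out)) {
    warning("unknown instruction(s): ",
            paste(unique(instruction[is.na(out)]), collapse = "; "))
  }
  out
}
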