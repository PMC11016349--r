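# Package-wide constants. Axis order is load-bearing: every pose, log
# column set, and report record uses this order.

POSE_AXES <- c("lat_mm", "lng_mm", "vrt_mm", "yaw_deg", "pitch_deg", "roll_deg")
TRANSLATION_AXES <- POSE_AXES[1:3]
ROTATION_AXES <- POSE_AXES[4:6]

`%||%` <- function(a, b) if (is.null(a)) b else a
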