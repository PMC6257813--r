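Package: audionav
Title: Agent-Based Simulation and Trajectory Analysis of Spatialized-Audio
    Navigation Aids
Version: 0.1.0
Authors@R:
    person("audionav", "developers", email = "audionav@example.org",
           role = c("aut", "cre"))
Description: A hardware-free simulator and analysis toolkit for
    cognitive-assistant navigation for the blind. Implements the audio
    interaction logic of an augmented-reality assistant (talking objects in
    scan, spotlight and target modes, a virtual guide that leads the user
    along a waypoint path, collision warnings, and a raw image-to-spectrogram
    sonification baseline), stochastic user-agent models calibrated to
    measured auditory localization errors, a desk-scale task battery
    (localization, spatial memory, direct navigation, long-range guided
    navigation, and virtual-reality benchmark tasks), and the trajectory
    metrics used to score them: moving-average smoothing, path length,
    deviation index, phase segmentation, percentile walking speed, circular
    aiming statistics, recall regression, and the Rayleigh test of circular
    uniformity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
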