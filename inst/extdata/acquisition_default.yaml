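# Five-LED bank, switch thresholds at the centers of LEDs 2 and 4,
# 2 ms LED response + 33 ms exposure per wavelength.
led_centers_nm: [730, 740, 756, 777, 805]
led_response_ms: 2
exposure_ms: 33
thresholds_nm: [740, 777]
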