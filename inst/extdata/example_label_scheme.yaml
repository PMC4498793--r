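# Example label-scheme config for load_label_volume(): maps the five tissue
# roles to the integer codes a third-party segmentation uses.
BG: 0
UWM: 7
CoGM: 5
CSF: 6
OTHER: 9
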