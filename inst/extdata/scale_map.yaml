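# Item-to-scale map for EMA scoring. Reversed items are answered on an
# inverted 7-point scale and are re-inverted (v -> 8 - v) before summing.
event_stress:
  items: [event_1, event_2, event_3]
  reversed: [event_3]
activity_stress:
  items: [activity_1, activity_2, activity_3]
  reversed: [activity_3]
social_stress:
  items: [social_1, social_2, social_3]
  reversed: [social_3]
physical_stress:
  items: [physical_1, physical_2, physical_3]
  reversed: [physical_3]
pa:
  items: [pa_1, pa_2, pa_3, pa_4]
  reversed: [pa_4]
"na":
  items: [na_1, na_2, na_3, na_4, na_5]
  reversed: [na_5]
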