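space_id,name,type,lat,lon
gs001,park 1,park,52.383840816505256,4.893246110994369
gs002,forest 2,forest,52.36678366070613,4.972202137019485
gs003,walking trail 3,walking_trail,52.31681679491885,4.850500235753134
gs004,park 4,park,52.334286796748636,4.916161267459392
gs005,forest 5,forest,52.36664428119548,4.8011866513639685
gs006,walking trail 6,walking_trail,52.303015738045794,4.938373187975958
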