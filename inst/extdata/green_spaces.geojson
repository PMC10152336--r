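{"type":"FeatureCollection","features":[{"type":"Feature","geometry":{"type":"Point","coordinates":[4.89324611099437,52.3838408165053]},"properties":{"space_id":"gs001","name":"park 1","type":"park"}},{"type":"Feature","geometry":{"type":"Point","coordinates":[4.97220213701948,52.3667836607061]},"properties":{"space_id":"gs002","name":"forest 2","type":"forest"}},{"type":"Feature","geometry":{"type":"Point","coordinates":[4.85050023575313,52.3168167949189]},"properties":{"space_id":"gs003","name":"walking trail 3","type":"walking_trail"}},{"type":"Feature","geometry":{"type":"Point","coordinates":[4.91616126745939,52.3342867967486]},"properties":{"space_id":"gs004","name":"park 4","type":"park"}},{"type":"Feature","geometry":{"type":"Point","coordinates":[4.80118665136397,52.3666442811955]},"properties":{"space_id":"gs005","name":"forest 5","type":"forest"}},{"type":"Feature","geometry":{"type":"Point","coordinates":[4.93837318797596,52.3030157380458]},"properties":{"space_id":"gs006","name":"walking trail 6","type":"walking_trail"}}]}
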