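{"channels":[{"channel":1,"source_id":1,"detector_id":2,"row":1,"col":1.5},{"channel":2,"source_id":4,"detector_id":2,"row":1,"col":2.5},{"channel":3,"source_id":4,"detector_id":5,"row":1,"col":3.5},{"channel":4,"source_id":7,"detector_id":5,"row":1,"col":4.5},{"channel":5,"source_id":7,"detector_id":8,"row":1,"col":5.5},{"channel":6,"source_id":10,"detector_id":8,"row":1,"col":6.5},{"channel":7,"source_id":10,"detector_id":11,"row":1,"col":7.5},{"channel":8,"source_id":13,"detector_id":11,"row":1,"col":8.5},{"channel":9,"source_id":13,"detector_id":14,"row":1,"col":9.5},{"channel":10,"source_id":16,"detector_id":14,"row":1,"col":10.5},{"channel":11,"source_id":1,"detector_id":1,"row":1.5,"col":1},{"channel":12,"source_id":3,"detector_id":2,"row":1.5,"col":2},{"channel":13,"source_id":4,"detector_id":4,"row":1.5,"col":3},{"channel":14,"source_id":6,"detector_id":5,"row":1.5,"col":4},{"channel":15,"source_id":7,"detector_id":7,"row":1.5,"col":5},{"channel":16,"source_id":9,"detector_id":8,"row":1.5,"col":6},{"channel":17,"source_id":10,"detector_id":10,"row":1.5,"col":7},{"channel":18,"source_id":12,"detector_id":11,"row":1.5,"col":8},{"channel":19,"source_id":13,"detector_id":13,"row":1.5,"col":9},{"channel":20,"source_id":15,"detector_id":14,"row":1.5,"col":10},{"channel":21,"source_id":16,"detector_id":16,"row":1.5,"col":11},{"channel":22,"source_id":3,"detector_id":1,"row":2,"col":1.5},{"channel":23,"source_id":3,"detector_id":4,"row":2,"col":2.5},{"channel":24,"source_id":6,"detector_id":4,"row":2,"col":3.5},{"channel":25,"source_id":6,"detector_id":7,"row":2,"col":4.5},{"channel":26,"source_id":9,"detector_id":7,"row":2,"col":5.5},{"channel":27,"source_id":9,"detector_id":10,"row":2,"col":6.5},{"channel":28,"source_id":12,"detector_id":10,"row":2,"col":7.5},{"channel":29,"source_id":12,"detector_id":13,"row":2,"col":8.5},{"channel":30,"source_id":15,"detector_id":13,"row":2,"col":9.5},{"channel":31,"source_id":15,"detector_id":16,"row":2,"col":10.5},{"channel":32,"source_id":2,"detector_id":1,"row":2.5,"col":1},{"channel":33,"source_id":3,"detector_id":3,"row":2.5,"col":2},{"channel":34,"source_id":5,"detector_id":4,"row":2.5,"col":3},{"channel":35,"source_id":6,"detector_id":6,"row":2.5,"col":4},{"channel":36,"source_id":8,"detector_id":7,"row":2.5,"col":5},{"channel":37,"source_id":9,"detector_id":9,"row":2.5,"col":6},{"channel":38,"source_id":11,"detector_id":10,"row":2.5,"col":7},{"channel":39,"source_id":12,"detector_id":12,"row":2.5,"col":8},{"channel":40,"source_id":14,"detector_id":13,"row":2.5,"col":9},{"channel":41,"source_id":15,"detector_id":15,"row":2.5,"col":10},{"channel":42,"source_id":17,"detector_id":16,"row":2.5,"col":11},{"channel":43,"source_id":2,"detector_id":3,"row":3,"col":1.5},{"channel":44,"source_id":5,"detector_id":3,"row":3,"col":2.5},{"channel":45,"source_id":5,"detector_id":6,"row":3,"col":3.5},{"channel":46,"source_id":8,"detector_id":6,"row":3,"col":4.5},{"channel":47,"source_id":8,"detector_id":9,"row":3,"col":5.5},{"channel":48,"source_id":11,"detector_id":9,"row":3,"col":6.5},{"channel":49,"source_id":11,"detector_id":12,"row":3,"col":7.5},{"channel":50,"source_id":14,"detector_id":12,"row":3,"col":8.5},{"channel":51,"source_id":14,"detector_id":15,"row":3,"col":9.5},{"channel":52,"source_id":17,"detector_id":15,"row":3,"col":10.5}],"roi_map":{"1":"TL(R)","2":"TL(R)","3":"DLPFC(R)","4":"DLPFC(R)","5":"mPFC(R)","6":"mPFC(L)","7":"mPFC(L)","8":"DLPFC(L)","9":"DLPFC(L)","10":"TL(L)","11":"TL(R)","12":"TL(R)","13":"DLPFC(R)","14":"DLPFC(R)","15":"mPFC(R)","16":"mPFC(R)","17":"mPFC(L)","18":"DLPFC(L)","19":"DLPFC(L)","20":"TL(L)","21":"TL(L)","22":"TL(R)","23":"TL(R)","24":"DLPFC(R)","25":"DLPFC(R)","26":"mPFC(R)","27":"mPFC(L)","28":"mPFC(L)","29":"DLPFC(L)","30":"DLPFC(L)","31":"TL(L)","32":"TL(R)","33":"TL(R)","34":"DLPFC(R)","35":"DLPFC(R)","36":"mPFC(R)","37":"mPFC(R)","38":"mPFC(L)","39":"DLPFC(L)","40":"DLPFC(L)","41":"TL(L)","42":"TL(L)","43":"TL(R)","44":"TL(R)","45":"DLPFC(R)","46":"DLPFC(R)","47":"mPFC(R)","48":"mPFC(L)","49":"mPFC(L)","50":"DLPFC(L)","51":"DLPFC(L)","52":"TL(L)"},"n_sources":17,"n_detectors":16,"distance_cm":3}
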