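{"diversity":[{"window":"W1","population":"P1","n_individuals":8,"rarefaction_g":16,"Ar":5,"He":0.77,"Ho":0.675,"F":0.123376623376623},{"window":"W1","population":"P2","n_individuals":8,"rarefaction_g":16,"Ar":4,"He":0.658333333333333,"Ho":0.7,"F":-0.0632911392405062},{"window":"W1","population":"P3","n_individuals":8,"rarefaction_g":16,"Ar":3.8,"He":0.696666666666667,"Ho":0.725,"F":-0.0406698564593302},{"window":"W1","population":"P4","n_individuals":8,"rarefaction_g":16,"Ar":3.2,"He":0.651666666666667,"Ho":0.65,"F":0.00255754475703329},{"window":"W2","population":"P1","n_individuals":8,"rarefaction_g":16,"Ar":4,"He":0.646666666666667,"Ho":0.7,"F":-0.0824742268041236},{"window":"W2","population":"P2","n_individuals":8,"rarefaction_g":16,"Ar":4.4,"He":0.716666666666667,"Ho":0.775,"F":-0.0813953488372092},{"window":"W2","population":"P3","n_individuals":8,"rarefaction_g":16,"Ar":3.8,"He":0.581666666666667,"Ho":0.575,"F":0.011461318051576},{"window":"W2","population":"P4","n_individuals":8,"rarefaction_g":16,"Ar":3,"He":0.5,"Ho":0.6,"F":-0.2}],"differentiation":[{"window":"W1","pop1":"P1","pop2":"P2","Gst_dp":0.177530736371095,"Dps":0.3125,"distance_m":481.211924457203},{"window":"W1","pop1":"P1","pop2":"P3","Gst_dp":0.0447368421052629,"Dps":0.3,"distance_m":955.978498740798},{"window":"W1","pop1":"P1","pop2":"P4","Gst_dp":0.194195654513495,"Dps":0.3875,"distance_m":896.090219507226},{"window":"W1","pop1":"P2","pop2":"P3","Gst_dp":0.320017956919427,"Dps":0.4,"distance_m":0},{"window":"W1","pop1":"P2","pop2":"P4","Gst_dp":0.324244657332351,"Dps":0.425,"distance_m":0},{"window":"W1","pop1":"P3","pop2":"P4","Gst_dp":0.239578551599011,"Dps":0.3875,"distance_m":0},{"window":"W2","pop1":"P1","pop2":"P2","Gst_dp":0.142518358976709,"Dps":0.35,"distance_m":2186.80301056297},{"window":"W2","pop1":"P1","pop2":"P3","Gst_dp":0.194740185491044,"Dps":0.3625,"distance_m":1237.01986096137},{"window":"W2","pop1":"P1","pop2":"P4","Gst_dp":0.447388368246968,"Dps":0.4875,"distance_m":0},{"window":"W2","pop1":"P2","pop2":"P3","Gst_dp":0.359866224077168,"Dps":0.475,"distance_m":486.778554491094},{"window":"W2","pop1":"P2","pop2":"P4","Gst_dp":0.385159748486044,"Dps":0.4875,"distance_m":2310.91011333451},{"window":"W2","pop1":"P3","pop2":"P4","Gst_dp":0.476211935614704,"Dps":0.4625,"distance_m":1474.64391533327}],"report":[{"response":"Gst_dp","metric":"LWOOD_1:3","shape":"\\","importance":1,"r2_marginal":1,"r2_landscape":0.84877523227871,"pct_landscape":84.877523227871,"variant":"crops"},{"response":"Gst_dp","metric":"LFRINGE_1:3","shape":"X","importance":1,"r2_marginal":1,"r2_landscape":0.84877523227871,"pct_landscape":84.877523227871,"variant":"crops"},{"response":"Gst_dp","metric":"O:P_LFRINGE_1:3","shape":"X","importance":1,"r2_marginal":1,"r2_landscape":0.84877523227871,"pct_landscape":84.877523227871,"variant":"crops"},{"response":"Gst_dp","metric":"pc_GRASS_1:2.RAPE_1:3.MAIZE_1:3.CEREAL_1:3.SETTLE_1:3.LWATER_1:2.LROAD_1:2","shape":"\\","importance":1,"r2_marginal":1,"r2_landscape":0.84877523227871,"pct_landscape":84.877523227871,"variant":"crops"},{"response":"Dps","metric":"O:P_LWOOD_1:3","shape":"\\","importance":1,"r2_marginal":0.238951241515016,"r2_landscape":0.0929986469246375,"pct_landscape":38.9195077351349,"variant":"arable"},{"response":"Dps","metric":"LFRINGE_1:3","shape":"X","importance":1,"r2_marginal":0.238951241515016,"r2_landscape":0.0929986469246375,"pct_landscape":38.9195077351349,"variant":"arable"},{"response":"Dps","metric":"O:P_LFRINGE_1:3","shape":"X","importance":1,"r2_marginal":0.238951241515016,"r2_landscape":0.0929986469246375,"pct_landscape":38.9195077351349,"variant":"arable"},{"response":"Dps","metric":"pc_ARABLE_1:3.SETTLE_1:2.LWATER_1:3.LROAD_1:3","shape":"\\","importance":1,"r2_marginal":0.238951241515016,"r2_landscape":0.0929986469246375,"pct_landscape":38.9195077351349,"variant":"arable"}],"coefficients":{"Gst_dp":[{"term":"(Intercept)","estimate":-802.938901459584,"std.error":1.8333192538558e-143,"importance":1},{"term":"distance_m","estimate":48.9018642874031,"std.error":1.08638957125007e-144,"importance":1},{"term":"LWOOD_1to3","estimate":-11.2458889531782,"std.error":2.60792634858364e-145,"importance":1},{"term":"LFRINGE_1to3","estimate":498.142664159234,"std.error":1.13819567159599e-143,"importance":1},{"term":"OP_LFRINGE_1to3","estimate":-1566.73244765974,"std.error":3.57649851809471e-143,"importance":1},{"term":"LFRINGE_1to3__x__OP_LFRINGE_1to3","estimate":923.901763933375,"std.error":2.10949890260615e-143,"importance":1},{"term":"pc_GRASS_1to2.RAPE_1to3.MAIZE_1to3.CEREAL_1to3.SETTLE_1to3.LWATER_1to2.LROAD_1to2","estimate":-40.8580139372822,"std.error":8.85776065502933e-145,"importance":1}],"Dps":[{"term":"(Intercept)","estimate":4.52741371016002,"std.error":12.9916485731905,"importance":1},{"term":"distance_m","estimate":0.715344457274898,"std.error":1.82243150281876,"importance":1},{"term":"OP_LWOOD_1to3","estimate":-0.0641136890643535,"std.error":0.250045852235194,"importance":1},{"term":"LFRINGE_1to3","estimate":-2.59766343627146,"std.error":8.00692415568173,"importance":1},{"term":"OP_LFRINGE_1to3","estimate":7.91379923621196,"std.error":25.2567320274336,"importance":1},{"term":"LFRINGE_1to3__x__OP_LFRINGE_1to3","estimate":-5.20927092691741,"std.error":14.9266407032319,"importance":1},{"term":"pc_ARABLE_1to3.SETTLE_1to2.LWATER_1to3.LROAD_1to3","estimate":-1.20376807130411,"std.error":1.7676494648696,"importance":1}]},"r2":{"Gst_dp":{"marginal":1,"basic":0.15122476772129,"landscape":0.84877523227871,"pct_landscape":84.877523227871},"Dps":{"marginal":0.238951241515016,"basic":0.145952594590379,"landscape":0.0929986469246375,"pct_landscape":38.9195077351349}}}
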